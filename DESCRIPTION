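Package: trapbovw
Title: Bag-of-Visual-Words Classification of Insects on Yellow Sticky Traps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A bag-of-visual-words (BoVW) pipeline for detecting and
    classifying greenhouse pest insects and their natural enemies on
    yellow sticky traps. Provides SIFT local-descriptor extraction,
    k-means visual dictionaries, exact and k-d tree descriptor
    quantization, a stochastic-gradient-descent linear support vector
    machine, confusion-matrix evaluation with class-mean accuracy,
    sliding-window scene localization, and a synthetic trap-scene
    generator so the whole pipeline is testable without photographic
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
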