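#' BoVW pipeline configuration
#'
#' Bundles every choice the patch-classification pipeline depends on:
#' colour space, dictionary size, quantizer, histogram normalization, SIFT
#' detector parameters and SVM hyperparameters.  One config + one seed
#' determines the whole model deterministically.
#'
#' @param colour_space `"greyscale"`, `"rgb"` or `"hsv"`.
#' @param vocsize visual dictionary size.
#' @param quantizer `"kdtree"` (default, exact unless budgeted) or `"vq"`.
#' @param max_comparisons k-d tree backtracking budget; 0 = exact.
#' @param normalization BoVW histogram normalization.
#' @param sift a [sift_params()].
#' @param lambda,epochs,eta_bias SVM-SGD hyperparameters.
#' @param kmeans_max_iter,kmeans_n_init,kmeans_max_pool dictionary-build
#'   controls.
#' @param min_keypoints evidence floor: an image yielding fewer descriptors
#'   than this carries no usable signal (its L1 histogram would amplify one
#'   or two stray words), so it is classified as the background class when
#'   the model has one.
#' @param seed master seed for dictionary build and SVM shuffling.
#' @return a `bovw_config`.
#' @export
bovw_config <- function(colour_space = c("greyscale", "rgb", "hsv"),
                        vocsize = 200L,
                        quantizer = c("kdtree", "vq"),
                        max_comparisons = 0L,
                        normalization = c("l1", "none", "l2"),
                        sift = sift_params(),
                        lambda = 1e-4, epochs = 50L, eta_bias = 0.01,
                        kmeans_max_iter = 50L, kmeans_n_init = 3L,
                        kmeans_max_pool = 10000L,
                        min_keypoints = 4L,
                        seed = 1L) {
  structure(list(colour_space = match.arg(colour_space),
                 vocsize = as.integer(vocsize),
                 quantizer = match.arg(quantizer),
                 max_comparisons = as.integer(max_comparisons),
                 normalization = match.arg(normalization),
                 sift = sift, lambda = lambda, epochs = as.integer(epochs),
                 eta_bias = eta_bias,
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 kmeans_n_init = as.integer(kmeans_n_init),
                 kmeans_max_pool = as.integer(kmeans_max_pool),
                 min_keypoints = as.integer(min_keypoints),
                 seed = as.integer(seed)),
            class = "bovw_config")
}

#' Extract descriptors for every patch of a sub-image set
#'
#' @param set a `subimage_set`.
#' @param config a [bovw_config()] (colour space + SIFT parameters used).
#' @return list of `descriptor_set`s, one per patch.
#' @export
set_descriptors <- function(set, config) {
  stopifnot(inherits(set, "subimage_set"), inherits(config, "bovw_config"))
  lapply(set$patches, function(p)
    extract_descriptors(convert_colour(p, config$colour_space), config$sift))
}

quantize_with <- function(desc, dictionary, config) {
  if (config$quantizer == "vq") quantize_vq(desc, dictionary)
  else quantize_kdtree(desc, dictionary, config$max_comparisons,
                       report_mismatch = FALSE)
}

#' Encode a sub-image set as a BoVW feature matrix
#'
#' @param desc_sets list of `descriptor_set`s (from [set_descriptors()]).
#' @param dictionary a `visual_dictionary`.
#' @param config a [bovw_config()].
#' @return numeric matrix, one row per patch, with attribute `n_keypoints`.
#' @export
encode_set <- function(desc_sets, dictionary, config) {
  rows <- lapply(desc_sets, function(d) {
    v <- encode_bovw(quantize_with(d, dictionary, config),
                     dictionary$vocsize, config$normalization)
    v$counts
  })
  m <- do.call(rbind, rows)
  attr(m, "n_keypoints") <- vapply(desc_sets, function(d) nrow(d$descriptors),
                                   integer(1))
  m
}

#' Train the full BoVW patch classifier
#'
#' Runs the complete training arm on a labelled sub-image set: colour
#' conversion, SIFT extraction, k-means dictionary build (from these
#' patches only -- never feed test data here), quantization, BoVW encoding
#' and SVM-SGD fitting.
#'
#' @param train_set labelled `subimage_set`.
#' @param config a [bovw_config()].
#' @param class_order optional fixed class order for the SVM.
#' @param dictionary optional pre-built dictionary (skips the k-means
#'   stage); used when several models share one codebook.
#' @return a `bovw_model`: `dictionary`, `svm`, `config`, `classes`.
#' @export
train_bovw_classifier <- function(train_set, config = bovw_config(),
                                  class_order = NULL, dictionary = NULL) {
  desc <- set_descriptors(train_set, config)
  if (is.null(dictionary)) {
    pool <- do.call(rbind, lapply(desc, `[[`, "descriptors"))
    dictionary <- build_dictionary(pool, config$vocsize, seed = config$seed,
                                   max_iter = config$kmeans_max_iter,
                                   n_init = config$kmeans_n_init,
                                   max_pool = config$kmeans_max_pool,
                                   colour_space = config$colour_space)
  }
  x <- encode_set(desc, dictionary, config)
  svm <- train_svm_sgd(x, train_set$info$label, lambda = config$lambda,
                       epochs = config$epochs, eta_bias = config$eta_bias,
                       seed = config$seed, class_order = class_order)
  structure(list(dictionary = dictionary, svm = svm, config = config,
                 classes = svm$classes),
            class = "bovw_model")
}

#' @export
print.bovw_model <- function(x, ...) {
  cat(sprintf("<bovw_model: %s, vocsize %d, %s quantizer, classes %s>\n",
              x$config$colour_space, x$dictionary$vocsize, x$config$quantizer,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Classify the patches of a sub-image set
#'
#' @param model a `bovw_model`.
#' @param set a `subimage_set`.
#' @return list with `label`, `scores`, `low_confidence` (see
#'   [predict_label()]).
#' @export
predict_bovw <- function(model, set) {
  stopifnot(inherits(model, "bovw_model"))
  desc <- set_descriptors(set, model$config)
  x <- encode_set(desc, model$dictionary, model$config)
  pred <- predict_label(model$svm, x)
  apply_keypoint_floor(pred, attr(x, "n_keypoints"), model)
}

# images below the evidence floor default to the background class (if the
# model has one) and are flagged low-confidence
apply_keypoint_floor <- function(pred, n_keypoints, model) {
  floor_n <- model$config$min_keypoints %||% 0L
  bg <- "BKGRND"
  if (floor_n > 0L && bg %in% model$classes) {
    starved <- n_keypoints < floor_n
    pred$label[starved] <- bg
    pred$low_confidence <- pred$low_confidence | starved
  }
  pred
}
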