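# Shared fixtures, built once per test run and cached in-process.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# confusion matrix printed for the best-performing unpooled model evaluated
# on the independent greenhouse image set (input data for the evaluation
# arithmetic)
table6_matrix <- function() {
  m <- matrix(c(48, 1, 0, 4, 14,
                0, 7, 0, 0, 0,
                0, 0, 32, 0, 0,
                135, 4, 20, 228, 33,
                0, 0, 0, 0, 485),
              nrow = 5, byrow = TRUE,
              dimnames = list(c("BEMITA", "ENCAFO", "MACRPY", "TRIAVA", "BKGRND"),
                              c("BEMITA", "ENCAFO", "MACRPY", "TRIAVA", "BKGRND")))
  names(dimnames(m)) <- c("true", "predicted")
  structure(m, class = c("confusion_matrix", class(m)))
}

# its category-pooled counterpart (whiteflies merged before prediction)
table8_matrix <- function() {
  m <- matrix(c(412, 4, 9, 62,
                0, 7, 0, 0,
                0, 0, 32, 0,
                0, 0, 0, 485),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("BEM-TRI", "ENCAFO", "MACRPY", "BKGRND"),
                              c("BEM-TRI", "ENCAFO", "MACRPY", "BKGRND")))
  names(dimnames(m)) <- c("true", "predicted")
  structure(m, class = c("confusion_matrix", class(m)))
}

# small labelled patch sets shared across tests (full 201 px patches)
tiny_train_set <- function() fixture("tiny_train", function() {
  generate_dataset(stats::setNames(rep(30L, 5), trap_taxonomy()),
                   rng_seed = 421L, dataset_tag = "Lab0d")
})

tiny_test_set <- function() fixture("tiny_test", function() {
  generate_dataset(stats::setNames(rep(6L, 5), trap_taxonomy()),
                   rng_seed = 422L, dataset_tag = "Lab0d")
})

tiny_config <- function() bovw_config(colour_space = "greyscale", vocsize = 40L,
                                      epochs = 25L, seed = 99L)

tiny_model <- function() fixture("tiny_model", function() {
  train_bovw_classifier(tiny_train_set(), tiny_config(),
                        class_order = trap_taxonomy())
})

# a cached descriptor-set list for the tiny training set
tiny_descriptors <- function() fixture("tiny_descriptors", function() {
  set_descriptors(tiny_train_set(), tiny_config())
})

# deterministic random descriptor matrix (rows roughly SIFT-like)
random_descriptors <- function(n, seed, p = 128L) {
  with_seed_local(seed, matrix(stats::runif(n * p, 0, 255), n, p))
}

# local copy of the package-internal seed guard for test-side oracles
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# brute-force nearest-centre oracle via a full distance matrix (BLAS route,
# independent of the C++ scan)
vq_oracle <- function(x, centres) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centres))) -
    2 * x %*% t(centres) +
    outer(rep(1, nrow(x)), rowSums(centres^2))
  max.col(-d2, ties.method = "first")
}
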