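#' Train a multi-class linear SVM by stochastic gradient descent
#'
#' Fits one-vs-rest linear SVMs on BoVW vectors by minimizing the primal
#' hinge-loss + L2 objective with the Pegasos SGD scheme: step size
#' `1/(lambda * t)`, per-step shrinkage, and projection onto the ball of
#' radius `1/sqrt(lambda)`.  The bias term is unregularized and follows its
#' own decaying `eta_bias / t` step.  Sample visit order is reshuffled every
#' epoch under the given seed, so identical data + seed reproduce identical
#' weights.
#'
#' @param x numeric matrix, one row per BoVW vector (all with the same
#'   normalization), or a list of `bovw_vector`s.
#' @param labels class label per row.
#' @param lambda L2 regularization strength.
#' @param epochs passes over the data.
#' @param eta_bias bias step-size scale.
#' @param seed shuffling seed.
#' @param class_order optional explicit class order; fixes prediction
#'   tie-breaking.  Defaults to the sorted unique labels.
#' @return a `linear_svm` model: `weights` (K x p), `biases`, `classes`,
#'   `objective` (primal objective at each epoch end, summed over the K
#'   binary problems), training metadata.
#' @export
train_svm_sgd <- function(x, labels, lambda = 1e-4, epochs = 50L,
                          eta_bias = 0.01, seed = 1L, class_order = NULL) {
  if (is.list(x) && !is.matrix(x))
    x <- do.call(rbind, lapply(x, function(v) v$counts))
  stopifnot(is.matrix(x))
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stopf("have %d labels for %d vectors", length(labels), nrow(x))
  classes <- class_order %||% sort(unique(labels))
  assert_labels(labels, classes, "class")
  if (length(classes) < 2L) stopf("need at least 2 classes, got %d", length(classes))
  y <- match(labels, classes)
  n <- nrow(x)
  order_mat <- with_seed(seed, {
    matrix(unlist(lapply(seq_len(epochs), function(e) sample.int(n))), nrow = n)
  })
  fit <- svm_sgd_cpp(x, y, length(classes), lambda, order_mat, eta_bias)
  structure(list(weights = fit$weights,
                 biases = as.numeric(fit$biases),
                 classes = classes,
                 objective = as.numeric(fit$objective),
                 lambda = lambda, epochs = as.integer(epochs),
                 eta_bias = eta_bias, seed = as.integer(seed),
                 n_per_class = as.integer(table(factor(labels, classes)))),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm: %d classes (%s), %d features, lambda %.3g, %d epochs>\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              ncol(x$weights), x$lambda, x$epochs))
  invisible(x)
}

#' Predict classes from a linear SVM
#'
#' Computes the per-class decision scores `w . x + b` and returns the argmax
#' class; exact score ties resolve to the earlier class in the model's
#' stored class order.  A zero vector (a patch with no keypoints) falls back
#' to the biases alone and is flagged low-confidence.
#'
#' @param model a `linear_svm`.
#' @param x a numeric vector, matrix of row vectors, or `bovw_vector`(s).
#' @return list with `label` (character vector), `scores` (n x K matrix in
#'   class order), and `low_confidence` (no-keypoint flag per row).
#' @export
predict_label <- function(model, x) {
  stopifnot(inherits(model, "linear_svm"))
  if (inherits(x, "bovw_vector")) x <- matrix(x$counts, nrow = 1)
  if (is.list(x) && !is.matrix(x))
    x <- do.call(rbind, lapply(x, function(v) v$counts))
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(model$weights))
    stopf("vector length %d does not match model features %d",
          ncol(x), ncol(model$weights))
  scores <- x %*% t(model$weights) +
    matrix(model$biases, nrow(x), length(model$biases), byrow = TRUE)
  colnames(scores) <- model$classes
  pick <- max.col(scores, ties.method = "first")
  list(label = model$classes[pick],
       scores = scores,
       low_confidence = rowSums(abs(x)) == 0)
}

#' Persist / load a linear SVM as plain text
#'
#' Weights go to `<prefix>.tsv` (biases as the last column) and metadata to
#' `<prefix>.yml`.
#'
#' @param model a `linear_svm`.
#' @param prefix file path without extension.
#' @export
write_svm <- function(model, prefix) {
  stopifnot(inherits(model, "linear_svm"))
  utils::write.table(cbind(model$weights, model$biases), paste0(prefix, ".tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- model[c("classes", "objective", "lambda", "epochs", "eta_bias",
                  "seed", "n_per_class")]
  yaml::write_yaml(meta, paste0(prefix, ".yml"), precision = 15L)
  invisible(prefix)
}

#' @rdname write_svm
#' @export
read_svm <- function(prefix) {
  m <- as.matrix(utils::read.delim(paste0(prefix, ".tsv"), header = FALSE))
  dimnames(m) <- NULL
  meta <- yaml::read_yaml(paste0(prefix, ".yml"))
  structure(list(weights = m[, -ncol(m), drop = FALSE],
                 biases = as.numeric(m[, ncol(m)]),
                 classes = as.character(meta$classes),
                 objective = as.numeric(meta$objective),
                 lambda = as.numeric(meta$lambda),
                 epochs = as.integer(meta$epochs),
                 eta_bias = as.numeric(meta$eta_bias),
                 seed = as.integer(meta$seed),
                 n_per_class = as.integer(meta$n_per_class)),
            class = "linear_svm")
}
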