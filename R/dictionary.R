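as_descriptor_matrix <- function(x) {
  if (inherits(x, "descriptor_set")) return(x$descriptors)
  if (is.list(x) && !is.data.frame(x))
    return(do.call(rbind, lapply(x, as_descriptor_matrix)))
  if (is.matrix(x)) return(x)
  stopf("expected a descriptor matrix, descriptor_set, or list of them")
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance from the nearest centre chosen so far
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    min_d2 <- rowSums(sweep(x, 2, x[idx[1], ], "-")^2)
    for (i in 2:k) {
      if (all(min_d2 <= 0)) {
        remaining <- setdiff(seq_len(n), idx[seq_len(i - 1L)])
        idx[i] <- if (length(remaining) > 1L) sample(remaining, 1L) else remaining
      } else {
        idx[i] <- sample.int(n, 1L, prob = min_d2)
      }
      d2 <- rowSums(sweep(x, 2, x[idx[i], ], "-")^2)
      min_d2 <- pmin(min_d2, d2)
    }
  }
  x[idx, , drop = FALSE]
}

#' Build a k-means visual dictionary from a descriptor pool
#'
#' Clusters SIFT descriptors with Euclidean k-means; the cluster centres are
#' the visual words (code words) that all later quantization refers to.
#' Initialisation is k-means++ under a fixed seed, the best of `n_init`
#' restarts (lowest within-cluster sum of squares) is kept, and very large
#' pools are deterministically subsampled to `max_pool` rows first.  The
#' dictionary must be built from training-split descriptors only; feeding it
#' test descriptors leaks information into the codebook.
#'
#' @param pool descriptor matrix, `descriptor_set`, or list of either.
#' @param vocsize number of visual words (200 and 500 are the usual
#'   working sizes for this problem).
#' @param seed RNG seed making the build reproducible.
#' @param max_iter Lloyd iteration budget per restart.
#' @param n_init number of k-means++ restarts.
#' @param max_pool descriptor subsample cap before clustering.
#' @param colour_space free-text provenance tag stored in the metadata.
#' @return a `visual_dictionary`: `centres` (`vocsize x 128`) plus build
#'   metadata (`vocsize`, `seed`, `n_descriptors`, `inertia`,
#'   `colour_space`).
#' @export
build_dictionary <- function(pool, vocsize, seed = 1L, max_iter = 50L,
                             n_init = 3L, max_pool = 10000L,
                             colour_space = NA_character_) {
  x <- as_descriptor_matrix(pool)
  if (!is_count(vocsize) || vocsize < 1) stopf("vocsize must be a positive integer")
  if (nrow(x) < vocsize)
    stopf("descriptor pool (%d) is smaller than vocsize (%d)", nrow(x), vocsize)
  with_seed(seed, {
    if (nrow(x) > max_pool) x <- x[sample.int(nrow(x), max_pool), , drop = FALSE]
    best <- NULL
    for (init in seq_len(n_init)) {
      fit <- NULL
      for (attempt in 0:4) { # re-seed init if Lloyd hits an empty cluster
        centres0 <- kmeanspp_init(x, vocsize)
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(x, centers = centres0,
                                         iter.max = max_iter,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit)) break
      }
      if (is.null(fit)) stopf("k-means failed to produce %d non-empty clusters", vocsize)
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    centres <- unname(best$centers)
    structure(list(centres = centres,
                   vocsize = as.integer(vocsize),
                   seed = as.integer(seed),
                   n_descriptors = nrow(x),
                   inertia = best$tot.withinss,
                   colour_space = colour_space),
              class = "visual_dictionary")
  })
}

#' @export
print.visual_dictionary <- function(x, ...) {
  cat(sprintf("<visual_dictionary: %d words x %d dims, inertia %.4g, built from %d descriptors (seed %d)>\n",
              x$vocsize, ncol(x$centres), x$inertia, x$n_descriptors, x$seed))
  invisible(x)
}

#' Quantize descriptors by exhaustive vector quantization
#'
#' Assigns every descriptor to its exact Euclidean-nearest visual word by an
#' exhaustive scan of the dictionary; ties go to the lowest word index.
#'
#' @param descriptors `descriptor_set` or `n x 128` matrix.
#' @param dictionary a [build_dictionary()] result.
#' @return integer vector of 1-based word indices (length `n`).
#' @export
quantize_vq <- function(descriptors, dictionary) {
  stopifnot(inherits(dictionary, "visual_dictionary"))
  x <- as_descriptor_matrix(descriptors)
  if (nrow(x) == 0L) return(integer(0))
  vq_assign_cpp(x, dictionary$centres)
}

#' Quantize descriptors with a max-variance k-d tree
#'
#' Builds a k-d tree over the dictionary by recursively splitting on the
#' dimension of maximum variance, then searches it per descriptor.  With
#' `max_comparisons = 0` (unlimited backtracking) the search is exact and
#' agrees with [quantize_vq()]; a positive budget gives the approximate
#' nearest-neighbour mode, in which case the fraction of assignments that
#' deviate from the exact answer is measured and attached as the
#' `mismatch_rate` attribute rather than silently ignored.
#'
#' @param descriptors `descriptor_set` or matrix.
#' @param dictionary a `visual_dictionary`.
#' @param max_comparisons distance-computation budget per query; `0` means
#'   exact.
#' @param leaf_size points per tree leaf.
#' @param report_mismatch measure the approximate-mode error rate against
#'   the exact assignment (only consulted when `max_comparisons > 0`).
#' @return integer vector of 1-based word indices, with attributes
#'   `comparisons` (per-descriptor distance computations) and, in
#'   approximate mode, `mismatch_rate`.
#' @export
quantize_kdtree <- function(descriptors, dictionary, max_comparisons = 0L,
                            leaf_size = 8L, report_mismatch = TRUE) {
  stopifnot(inherits(dictionary, "visual_dictionary"))
  x <- as_descriptor_matrix(descriptors)
  if (nrow(x) == 0L) return(integer(0))
  res <- kdtree_assign_cpp(x, dictionary$centres, as.integer(max_comparisons),
                           as.integer(leaf_size))
  out <- res$assignments
  attr(out, "comparisons") <- res$comparisons
  if (max_comparisons > 0L && report_mismatch) {
    exact <- vq_assign_cpp(x, dictionary$centres)
    attr(out, "mismatch_rate") <- mean(out != exact)
  }
  out
}

#' Encode word assignments as a bag-of-visual-words frequency vector
#'
#' Counts how many descriptors fell on each visual word; this frequency
#' vector is the image's BoVW "footprint" and the classifier's input.
#' L1 normalization (the default downstream) makes patches with different
#' keypoint counts comparable.
#'
#' @param assignments integer vector of 1-based word indices.
#' @param vocsize dictionary size.
#' @param normalization `"none"`, `"l1"`, or `"l2"`.
#' @return a `bovw_vector`: `counts` (length `vocsize`), `n_keypoints`,
#'   `normalization`.
#' @export
encode_bovw <- function(assignments, vocsize,
                        normalization = c("none", "l1", "l2")) {
  normalization <- match.arg(normalization)
  assignments <- as.integer(assignments)
  if (length(assignments) &&
      (anyNA(assignments) || min(assignments) < 1L || max(assignments) > vocsize))
    stopf("assignment indices must lie in 1..vocsize (%d)", vocsize)
  counts <- tabulate(assignments, nbins = vocsize)
  n <- length(assignments)
  counts <- switch(normalization,
    none = as.numeric(counts),
    l1 = if (n > 0) counts / n else as.numeric(counts),
    l2 = if (n > 0) counts / sqrt(sum(counts^2)) else as.numeric(counts))
  structure(list(counts = counts, n_keypoints = n,
                 normalization = normalization),
            class = "bovw_vector")
}

#' Persist / load a visual dictionary as plain text
#'
#' Centres go to `<prefix>.tsv` (tab-delimited matrix) and build metadata to
#' `<prefix>.yml`.
#'
#' @param dictionary a `visual_dictionary`.
#' @param prefix file path without extension.
#' @return `write_dictionary()` returns the prefix invisibly;
#'   `read_dictionary()` returns the dictionary.
#' @export
write_dictionary <- function(dictionary, prefix) {
  stopifnot(inherits(dictionary, "visual_dictionary"))
  utils::write.table(dictionary$centres, paste0(prefix, ".tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- dictionary[c("vocsize", "seed", "n_descriptors", "inertia", "colour_space")]
  yaml::write_yaml(meta, paste0(prefix, ".yml"), precision = 15L)
  invisible(prefix)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(prefix) {
  centres <- as.matrix(utils::read.delim(paste0(prefix, ".tsv"), header = FALSE))
  dimnames(centres) <- NULL
  meta <- yaml::read_yaml(paste0(prefix, ".yml"))
  structure(list(centres = centres,
                 vocsize = as.integer(meta$vocsize),
                 seed = as.integer(meta$seed),
                 n_descriptors = as.integer(meta$n_descriptors),
                 inertia = as.numeric(meta$inertia),
                 colour_space = meta$colour_space %||% NA_character_),
            class = "visual_dictionary")
}
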