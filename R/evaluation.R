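#' Build a confusion matrix
#'
#' Rows are true classes and columns predicted classes, in the given class
#' order; entry (i, j) counts records of true class i predicted as j.
#'
#' @param true,predicted equal-length label vectors.
#' @param class_order character vector fixing row/column order; both label
#'   vectors must be subsets of it.
#' @return K x K integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true, predicted, class_order = NULL) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stopf("true (%d) and predicted (%d) differ in length",
          length(true), length(predicted))
  class_order <- class_order %||% sort(unique(c(true, predicted)))
  assert_labels(c(true, predicted), class_order, "class")
  cm <- table(factor(true, class_order), factor(predicted, class_order))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("true", "predicted")
  structure(cm, class = c("confusion_matrix", class(cm)))
}

#' Per-class precision and recall from a confusion matrix
#'
#' For class i, recall = TP / (TP + FN) = `cm[i,i] / rowsum_i` and
#' precision = TP / (TP + FP) = `cm[i,i] / colsum_i`, reported as
#' percentages rounded half-up to 2 decimal places.  A class that was never
#' predicted has undefined precision (and one never observed, undefined
#' recall); such cells are `NA` and are excluded from the class means.
#'
#' @param cm a [confusion_matrix()] (or plain square matrix with dimnames).
#' @return a `metrics_report`: data frame `per_class` (class, recall,
#'   precision, n_true, n_predicted), plus `class_mean_recall`,
#'   `class_mean_precision` (unweighted means of the defined per-class
#'   values), `overall_accuracy` (trace/total), and `undefined` policy tag.
#' @export
precision_recall <- function(cm) {
  cm <- as.matrix(unclass(cm))
  if (nrow(cm) == 0L || nrow(cm) != ncol(cm)) stopf("confusion matrix must be square and non-empty")
  if (sum(cm) == 0) stopf("confusion matrix is empty (no records)")
  classes <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  tp <- diag(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  recall <- ifelse(rs > 0, 100 * tp / rs, NA_real_)
  precision <- ifelse(cs > 0, 100 * tp / cs, NA_real_)
  per_class <- data.frame(class = classes,
                          recall = round_half_up(recall, 2),
                          precision = round_half_up(precision, 2),
                          n_true = as.integer(rs),
                          n_predicted = as.integer(cs),
                          row.names = NULL)
  structure(list(per_class = per_class,
                 class_mean_recall = round_half_up(mean(recall, na.rm = TRUE), 2),
                 class_mean_precision = round_half_up(mean(precision, na.rm = TRUE), 2),
                 overall_accuracy = round_half_up(100 * sum(tp) / sum(cm), 2),
                 undefined = "excluded from class means"),
            class = "metrics_report")
}

#' Class-mean accuracy
#'
#' The unweighted arithmetic mean of the defined per-class values of one
#' metric, the headline "class mean" figure of the evaluation tables.
#'
#' @param report a `metrics_report`.
#' @param metric `"recall"` or `"precision"`.
#' @return percentage at 2 decimal places.
#' @export
class_mean <- function(report, metric = c("recall", "precision")) {
  stopifnot(inherits(report, "metrics_report"))
  metric <- match.arg(metric)
  v <- report$per_class[[metric]]
  if (all(is.na(v))) stopf("all per-class %s values are undefined", metric)
  round_half_up(mean(v, na.rm = TRUE), 2)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-class metrics (%):\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("Class-mean recall: %.2f   class-mean precision: %.2f   overall accuracy: %.2f\n",
              x$class_mean_recall, x$class_mean_precision, x$overall_accuracy))
  invisible(x)
}

#' Post-hoc pooling of a confusion matrix (diagnostic only)
#'
#' Sums the rows and columns of the given classes into one pooled class.
#' Metrics computed from a post-hoc pooled matrix are a diagnostic: they
#' are not equivalent to a model trained and applied with pooled labels,
#' because cross-confusions between the pooled members become true
#' positives only at the matrix level.  The result is tagged accordingly.
#'
#' @param cm a `confusion_matrix`.
#' @param members classes to merge.
#' @param pooled_label name of the merged class.
#' @return pooled `confusion_matrix` with attribute `post_hoc = TRUE`.
#' @export
pool_confusion_matrix <- function(cm, members = c("BEMITA", "TRIAVA"),
                                  pooled_label = "BEM-TRI") {
  cm <- as.matrix(unclass(cm))
  stopifnot(all(members %in% rownames(cm)))
  keep <- setdiff(rownames(cm), members)
  pr <- colSums(cm[members, , drop = FALSE])
  m2 <- rbind(matrix(pr, 1, dimnames = list(pooled_label, colnames(cm))),
              cm[keep, , drop = FALSE])
  pc <- rowSums(m2[, members, drop = FALSE])
  m3 <- cbind(matrix(pc, ncol = 1, dimnames = list(rownames(m2), pooled_label)),
              m2[, keep, drop = FALSE])
  names(dimnames(m3)) <- c("true", "predicted")
  structure(m3, class = c("confusion_matrix", class(m3)), post_hoc = TRUE)
}

#' Render a model grid's metrics as an aligned text table
#'
#' Mirrors the evaluation-table layout: a recall block then a precision
#' block, one row per model, one column per class plus the class mean, all
#' at 2 decimal places.  [parse_report()] inverts the rendering.
#'
#' @param reports named list of `metrics_report`s (names = model ids).
#' @param file optional path; when given the table is also written there.
#' @return the rendered lines, invisibly when `file` is given.
#' @export
render_report <- function(reports, file = NULL) {
  stopifnot(length(reports) > 0)
  classes <- reports[[1]]$per_class$class
  ids <- names(reports) %||% as.character(seq_along(reports))
  fmt_val <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f", v))
  block <- function(metric) {
    head <- paste(c("model_id", classes, "class_mean"), collapse = "\t")
    rows <- vapply(seq_along(reports), function(i) {
      r <- reports[[i]]
      stopifnot(identical(r$per_class$class, classes))
      cm <- if (metric == "recall") r$class_mean_recall else r$class_mean_precision
      paste(c(ids[i], fmt_val(r$per_class[[metric]]), fmt_val(cm)), collapse = "\t")
    }, character(1))
    c(paste0("# ", metric, " in %"), head, rows)
  }
  lines <- c(block("recall"), "", block("precision"))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' @rdname render_report
#' @param lines character vector as produced by `render_report()` (or a
#'   file path).
#' @export
parse_report <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^# ", lines)
  stopifnot(length(starts) == 2L)
  read_block <- function(from, to) {
    head <- strsplit(lines[from + 1L], "\t", fixed = TRUE)[[1]]
    rows <- lapply(lines[seq(from + 2L, to)], function(l)
      strsplit(l, "\t", fixed = TRUE)[[1]])
    list(classes = head[2:(length(head) - 1L)],
         ids = vapply(rows, `[`, character(1), 1L),
         values = lapply(rows, function(r) suppressWarnings(as.numeric(r[-1L]))))
  }
  rec <- read_block(starts[1], starts[2] - 1L)
  pre <- read_block(starts[2], length(lines))
  stopifnot(identical(rec$ids, pre$ids), identical(rec$classes, pre$classes))
  k <- length(rec$classes)
  out <- lapply(seq_along(rec$ids), function(i) {
    structure(list(
      per_class = data.frame(class = rec$classes,
                             recall = rec$values[[i]][seq_len(k)],
                             precision = pre$values[[i]][seq_len(k)],
                             n_true = NA_integer_, n_predicted = NA_integer_,
                             row.names = NULL),
      class_mean_recall = rec$values[[i]][k + 1L],
      class_mean_precision = pre$values[[i]][k + 1L],
      overall_accuracy = NA_real_,
      undefined = "excluded from class means"), class = "metrics_report")
  })
  names(out) <- rec$ids
  out
}

#' Write / read a confusion matrix as tab-delimited text
#' @param cm a `confusion_matrix`.
#' @param path file path.
#' @export
write_confusion_matrix <- function(cm, path) {
  m <- as.matrix(unclass(cm))
  utils::write.table(cbind(true = rownames(m), as.data.frame(m)), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_confusion_matrix
#' @export
read_confusion_matrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  names(dimnames(m)) <- c("true", "predicted")
  structure(m, class = c("confusion_matrix", class(m)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- as.matrix(unclass(x))
  attr(m, "post_hoc") <- NULL
  print(m)
  if (isTRUE(attr(x, "post_hoc")))
    cat("(post-hoc pooled matrix: diagnostic only, not a pooled-model result)\n")
  invisible(x)
}
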