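#' Sliding-window classification of a full trap scene
#'
#' Classifies every `window x window` cell of a regular grid over the scene
#' through the identical patch pipeline (colour conversion, SIFT,
#' quantization, BoVW encoding, SVM prediction).  The grid covers the scene
#' interior where a full window fits; the background class is what keeps
#' empty regions from being forced into an insect class.
#'
#' @param scene `h x w x 3` array, 8-bit valued.
#' @param model a `bovw_model`.
#' @param window odd window edge length (must match the training patch
#'   size for the pipeline-identity property).
#' @param stride grid step in px (>= 1).
#' @return a `category_map` data frame with 0-based window-centre
#'   coordinates `x`, `y`, the winning `label` and its decision `score`;
#'   the full score matrix is attached as attribute `scores`.
#' @export
scan_scene <- function(scene, model, window = 201L, stride = 25L) {
  stopifnot(inherits(model, "bovw_model"), stride >= 1L)
  dims <- dim(scene)
  h <- dims[1]; w <- dims[2]
  if (h < window || w < window)
    stopf("scene %dx%d is smaller than the %d px window", w, h, window)
  half <- (window - 1L) %/% 2L
  lefts <- seq.int(0L, w - window, by = stride)   # 0-based top-left corners
  tops <- seq.int(0L, h - window, by = stride)
  grid <- expand.grid(left = lefts, top = tops)
  labels <- character(nrow(grid))
  all_scores <- matrix(NA_real_, nrow(grid), length(model$classes),
                       dimnames = list(NULL, model$classes))
  for (i in seq_len(nrow(grid))) {
    ri <- (grid$top[i] + 1L):(grid$top[i] + window)
    ci <- (grid$left[i] + 1L):(grid$left[i] + window)
    patch <- scene[ri, ci, , drop = FALSE]
    desc <- extract_descriptors(convert_colour(patch, model$config$colour_space),
                                model$config$sift)
    v <- encode_bovw(quantize_with(desc, model$dictionary, model$config),
                     model$dictionary$vocsize, model$config$normalization)
    pred <- apply_keypoint_floor(predict_label(model$svm, v$counts),
                                 v$n_keypoints, model)
    labels[i] <- pred$label
    all_scores[i, ] <- pred$scores
  }
  out <- data.frame(x = grid$left + half, y = grid$top + half,
                    label = labels,
                    score = all_scores[cbind(seq_len(nrow(grid)),
                                             match(labels, model$classes))])
  attr(out, "scores") <- all_scores
  attr(out, "window") <- as.integer(window)
  attr(out, "stride") <- as.integer(stride)
  class(out) <- c("category_map", "data.frame")
  out
}

#' Extract point detections from a category map
#'
#' Keeps non-background cells with decision score at least `min_score`,
#' then applies greedy per-class non-maximum suppression: cells are visited
#' in order (score descending, ties by y then x) and a cell is kept only if
#' no kept cell of the same class lies within `suppression_radius`.  With
#' `refine = "centroid"` each kept detection is relocated to the
#' score-weighted centroid of its same-class cells within the suppression
#' radius, which recovers object centres from the plateau of windows that
#' all contain the insect.
#'
#' @param map a `category_map`.
#' @param min_score minimum decision score (the linear SVM margin).
#' @param suppression_radius same-class suppression distance in px.  The
#'   default is about half the analysis window: a window classifies as an
#'   insect wherever the insect lies fully inside it, so one individual
#'   produces a response plateau roughly one window wide.
#' @param refine `"centroid"` (iterative score-weighted centroid of the
#'   same-class response plateau, recovering the object centre) or
#'   `"none"` (keep the raw winning cell).
#' @param cross_class after per-class suppression, also drop detections of
#'   a different class within the radius of a stronger detection (one
#'   individual can otherwise surface under two confusable classes).
#' @param background_label label treated as background.
#' @return a `detection_list` data frame (x, y, label, score).
#' @export
extract_detections <- function(map, min_score = 0, suppression_radius = 140,
                               refine = c("centroid", "none"),
                               cross_class = TRUE,
                               background_label = "BKGRND") {
  refine <- match.arg(refine)
  # plateau membership uses every non-background winning cell regardless of
  # score; min_score gates only the final peak (a low-score cell may still
  # be part of an object's response plateau)
  cand <- map[map$label != background_label, , drop = FALSE]
  empty <- structure(data.frame(x = integer(), y = integer(),
                                label = character(), score = numeric()),
                     class = c("detection_list", "data.frame"))
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(-cand$score, cand$y, cand$x), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    same <- kept[cand$label[kept] == cand$label[i]]
    if (length(same) == 0L ||
        min(sqrt((cand$x[same] - cand$x[i])^2 + (cand$y[same] - cand$y[i])^2)) >
          suppression_radius) kept <- c(kept, i)
  }
  out <- cand[kept, c("x", "y", "label", "score"), drop = FALSE]
  if (refine == "centroid") {
    for (j in seq_len(nrow(out))) {
      cx <- out$x[j]; cy <- out$y[j]
      same <- cand[cand$label == out$label[j], , drop = FALSE]
      for (iter in 1:4) { # mean-shift towards the plateau centre
        near <- sqrt((same$x - cx)^2 + (same$y - cy)^2) <= suppression_radius
        cx <- mean(same$x[near])
        cy <- mean(same$y[near])
      }
      out$x[j] <- round(cx); out$y[j] <- round(cy)
    }
  }
  out <- out[out$score >= min_score, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  if (cross_class && nrow(out) > 1L) {
    out <- out[order(-out$score, out$y, out$x), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!keep[i]) next
      d <- sqrt((out$x - out$x[i])^2 + (out$y - out$y[i])^2)
      keep[d <= suppression_radius & seq_len(nrow(out)) > i] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("detection_list", "data.frame")
  out
}

#' Match detections against ground-truth markers
#'
#' One-to-one matching on the bipartite graph of same-class pairs within
#' `tolerance_px`: pairs are first accepted greedily in order of increasing
#' distance, then the matching is completed to maximum cardinality by
#' augmenting paths (pure nearest-first greedy can strand matchable pairs).
#' Matched pairs are true positives, leftover detections false positives,
#' leftover markers false negatives.
#'
#' @param detections a `detection_list`.
#' @param markers a `marker_table`.
#' @param tolerance_px maximum centre distance for a match.
#' @param scheme optional [pooling_scheme()] applied to both label sets
#'   before matching (e.g. BEM-TRI pooling).
#' @return list with `tp`, `fp`, `fn`, `recall`, `precision`, `per_class`
#'   data frame, and the matched index pairs.
#' @export
match_detections <- function(detections, markers, tolerance_px = 30,
                             scheme = NULL) {
  stopifnot(tolerance_px > 0)
  det_lab <- as.character(detections$label)
  mar_lab <- as.character(markers$label)
  if (!is.null(scheme)) {
    det_lab <- apply_pooling(det_lab, scheme)
    mar_lab <- apply_pooling(mar_lab, scheme)
  }
  nd <- nrow(detections); nm <- nrow(markers)
  pairs <- NULL
  if (nd > 0 && nm > 0) {
    d2 <- outer(detections$y, markers$y, "-")^2 + outer(detections$x, markers$x, "-")^2
    ok <- which(d2 <= tolerance_px^2 & outer(det_lab, mar_lab, "=="),
                arr.ind = TRUE)
    if (nrow(ok)) {
      ord <- order(d2[ok], ok[, 1], ok[, 2])
      ok <- ok[ord, , drop = FALSE]
      # candidate markers per detection, nearest first
      adj <- split(ok[, 2], factor(ok[, 1], levels = seq_len(nd)))
      match_d <- integer(nd); match_m <- integer(nm)
      # greedy nearest-first warm start
      for (i in seq_len(nrow(ok))) {
        if (!match_d[ok[i, 1]] && !match_m[ok[i, 2]]) {
          match_d[ok[i, 1]] <- ok[i, 2]
          match_m[ok[i, 2]] <- ok[i, 1]
        }
      }
      # complete to maximum cardinality by augmenting paths
      visited <- logical(nm)
      augment <- function(i) {
        for (j in adj[[i]]) {
          if (visited[j]) next
          visited[j] <<- TRUE
          if (match_m[j] == 0L || augment(match_m[j])) {
            match_d[i] <<- j
            match_m[j] <<- i
            return(TRUE)
          }
        }
        FALSE
      }
      for (i in seq_len(nd)) {
        if (match_d[i] == 0L && length(adj[[i]])) {
          visited <- logical(nm)
          augment(i)
        }
      }
      matched <- which(match_d > 0L)
      if (length(matched))
        pairs <- cbind(matched, match_d[matched])
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  fp <- nd - tp; fn <- nm - tp
  classes <- sort(unique(c(det_lab, mar_lab)))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tpc <- if (is.null(pairs)) 0L else sum(mar_lab[pairs[, 2]] == cl)
    data.frame(class = cl, tp = tpc,
               fp = sum(det_lab == cl) - tpc,
               fn = sum(mar_lab == cl) - tpc)
  }))
  list(tp = tp, fp = fp, fn = fn,
       recall = if (nm > 0) tp / nm else NA_real_,
       precision = if (nd > 0) tp / nd else NA_real_,
       per_class = per_class, pairs = pairs)
}

#' Export a category map as delimited text or a colour overlay
#'
#' @param map a `category_map`.
#' @param path output path (`.tsv` for the table form).
#' @export
write_category_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[c("x", "y", "label", "score")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_category_map
#' @param scene the scanned scene (for the overlay base).
#' @param colours named vector mapping labels to R colours; background
#'   cells are not drawn.
#' @param background_label label left undrawn.
#' @export
write_category_overlay <- function(map, scene, path,
                                   colours = c(BEMITA = "red", TRIAVA = "blue",
                                               "BEM-TRI" = "purple",
                                               ENCAFO = "black",
                                               MACRPY = "green"),
                                   background_label = "BKGRND") {
  img <- scene / 255
  stride <- attr(map, "stride") %||% 25L
  half <- max(2L, stride %/% 2L)
  for (i in seq_len(nrow(map))) {
    if (map$label[i] == background_label) next
    col <- colours[map$label[i]]
    if (is.na(col)) col <- "grey40"
    rgbv <- as.numeric(grDevices::col2rgb(col)) / 255
    ri <- max(1, map$y[i] + 1 - half):min(dim(img)[1], map$y[i] + 1 + half)
    ci <- max(1, map$x[i] + 1 - half):min(dim(img)[2], map$x[i] + 1 + half)
    for (k in 1:3) img[ri, ci, k] <- 0.5 * img[ri, ci, k] + 0.5 * rgbv[k]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Refine detections by keypoint back-projection and re-classification
#'
#' A BoVW histogram says *that* an insect is in the window, not *where*:
#' sliding-window plateau centroids are therefore only window-accurate.
#' This refinement recovers object-level positions from the model itself.
#' For each detection, iteratively: classify the window at the current
#' position; drop the detection if it resolves to background; otherwise
#' find the keypoints whose visual word carries positive SVM weight for
#' the predicted class (restricted to a radius around the window centre so
#' neighbouring objects do not pull), and move the detection to their
#' weight-averaged position.  Finally, detections that converged to the
#' same spot are merged, strongest first.
#'
#' @param detections a `detection_list` (from [extract_detections()]).
#' @param scene the scanned scene.
#' @param model the `bovw_model` used for scanning.
#' @param window analysis window size.
#' @param iterations refinement rounds.
#' @param bp_radius keypoint-selection radius around the window centre, per
#'   iteration (recycled).  The first pass is unrestricted (the whole
#'   window) so off-centre objects are reached; later passes tighten so
#'   neighbouring objects do not pull.
#' @param merge_radius detections closer than this after refinement are
#'   merged.
#' @return the refined `detection_list`.
#' @export
refine_detections <- function(detections, scene, model, window = 201L,
                              iterations = 2L, bp_radius = c(141, 60),
                              merge_radius = 60) {
  stopifnot(inherits(model, "bovw_model"))
  det <- as.data.frame(detections)
  if (!nrow(det)) return(detections)
  half <- (window - 1L) %/% 2L
  h <- dim(scene)[1]; w <- dim(scene)[2]
  drop <- logical(nrow(det))
  for (j in seq_len(nrow(det))) {
    for (it in seq_len(iterations)) {
      cx <- min(max(det$x[j], half), w - 1L - half)
      cy <- min(max(det$y[j], half), h - 1L - half)
      patch <- scene[(cy - half + 1L):(cy + half + 1L),
                     (cx - half + 1L):(cx + half + 1L), , drop = FALSE]
      d <- extract_descriptors(convert_colour(patch, model$config$colour_space),
                               model$config$sift)
      if (nrow(d$descriptors) == 0L) { drop[j] <- TRUE; break }
      a <- quantize_with(d, model$dictionary, model$config)
      v <- encode_bovw(a, model$dictionary$vocsize, model$config$normalization)
      pred <- apply_keypoint_floor(predict_label(model$svm, v$counts),
                                   v$n_keypoints, model)
      det$label[j] <- pred$label
      det$score[j] <- max(pred$scores)
      if (pred$label == "BKGRND") { drop[j] <- TRUE; break }
      k <- match(pred$label, model$svm$classes)
      wts <- model$svm$weights[k, a]
      rad <- bp_radius[min(it, length(bp_radius))]
      sel <- wts > 0 &
        sqrt((d$keypoints$x - half)^2 + (d$keypoints$y - half)^2) <= rad
      if (sum(sel) < 2L) break
      ww <- wts[sel]
      det$x[j] <- round(cx - half + sum(d$keypoints$x[sel] * ww) / sum(ww))
      det$y[j] <- round(cy - half + sum(d$keypoints$y[sel] * ww) / sum(ww))
    }
  }
  det <- det[!drop, , drop = FALSE]
  if (nrow(det) > 1L) {
    det <- det[order(-det$score, det$y, det$x), , drop = FALSE]
    keep <- rep(TRUE, nrow(det))
    for (i in seq_len(nrow(det))) {
      if (!keep[i]) next
      d2 <- sqrt((det$x - det$x[i])^2 + (det$y - det$y[i])^2)
      keep[d2 <= merge_radius & seq_len(nrow(det)) > i] <- FALSE
    }
    det <- det[keep, , drop = FALSE]
  }
  rownames(det) <- NULL
  class(det) <- c("detection_list", "data.frame")
  det
}

#' Detect and localize insects on a full trap scene
#'
#' The full localization chain: [scan_scene()], candidate extraction by
#' per-class non-maximum suppression (generous: no cross-class pass, since
#' refinement re-classifies every candidate), [refine_detections()], and a
#' final plateau-support filter.  Support is the number of same-class map
#' cells within the suppression radius of the refined position: a real
#' object is backed by a response plateau roughly one window wide, while
#' spurious candidates (partial-view halos that did not resolve onto their
#' object) have little support.  The default `min_support` corresponds to
#' about 12500 px^2 of plateau area and scales with the stride.
#'
#' @param scene `h x w x 3` array.
#' @param model a `bovw_model` (for spatial monitoring, typically trained
#'   with the pooled BEM-TRI taxonomy, mirroring the category maps of the
#'   original workflow).
#' @param window,stride scan grid parameters.
#' @param suppression_radius per-class suppression distance.
#' @param min_support minimum same-class plateau cells backing a
#'   detection.
#' @param ... passed to [refine_detections()].
#' @return a `detection_list`.
#' @export
detect_insects <- function(scene, model, window = 201L, stride = 25L,
                           suppression_radius = 140,
                           min_support = round(12500 / stride^2), ...) {
  map <- scan_scene(scene, model, window = window, stride = stride)
  det <- extract_detections(map, suppression_radius = suppression_radius,
                            cross_class = FALSE)
  det <- refine_detections(det, scene, model, window = window, ...)
  if (nrow(det) && min_support > 0) {
    cand <- map[map$label != "BKGRND", , drop = FALSE]
    support <- vapply(seq_len(nrow(det)), function(j)
      sum(cand$label == det$label[j] &
            sqrt((cand$x - det$x[j])^2 + (cand$y - det$y[j])^2) <=
              suppression_radius), numeric(1))
    det$support <- support
    det <- det[support >= min_support, , drop = FALSE]
    rownames(det) <- NULL
  }
  det
}

#' Convert detections to a marker table
#'
#' Detections re-expressed in the annotation format round-trip through
#' [write_markers()] / [read_markers()], so automatic and manual
#' annotations share one file dialect.
#'
#' @param detections a `detection_list`.
#' @param image_id source image identifier.
#' @param dataset_tag tag recorded for the detections.
#' @return a `marker_table`.
#' @export
detections_to_markers <- function(detections, image_id = "scene",
                                  dataset_tag = "detected") {
  as_marker_table(data.frame(
    image_id = rep(image_id, nrow(detections)),
    x = as.integer(detections$x), y = as.integer(detections$y),
    label = as.character(detections$label),
    dataset_tag = rep(dataset_tag, nrow(detections))), validate = FALSE)
}
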