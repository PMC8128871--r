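MARKER_COLUMNS <- c("image_id", "x", "y", "label", "dataset_tag")

empty_marker_table <- function() {
  data.frame(image_id = character(), x = integer(), y = integer(),
             label = character(), dataset_tag = character())
}

as_marker_table <- function(df, taxonomy = NULL, validate = TRUE) {
  stopifnot(is.data.frame(df), all(MARKER_COLUMNS %in% names(df)))
  df <- df[MARKER_COLUMNS]
  df$image_id <- as.character(df$image_id)
  df$x <- as.integer(df$x); df$y <- as.integer(df$y)
  df$label <- as.character(df$label)
  df$dataset_tag <- as.character(df$dataset_tag)
  if (validate && !is.null(taxonomy)) assert_labels(df$label, taxonomy)
  class(df) <- c("marker_table", "data.frame")
  df
}

#' Read and write point-marker annotation tables
#'
#' Marker tables are the plain-text record of manual annotation: one row
#' per insect, holding the source image id, the 0-based pixel position of
#' a point near the middle of the individual (x = column, y = row, origin
#' top-left), the class label, and a dataset tag (e.g. Lab0d, Lab7d).  The
#' on-disk dialect is tab-delimited UTF-8 with a header row.  `read_markers`
#' followed by `write_markers` is the identity.
#'
#' @param path file path.
#' @param taxonomy permitted labels; rows with labels outside it are
#'   rejected.
#' @param image_size optional `c(width, height)`; markers outside these
#'   bounds raise a validation error.
#' @return `read_markers()` returns a `marker_table` data frame.
#' @export
read_markers <- function(path, taxonomy = trap_taxonomy(), image_size = NULL) {
  if (!file.exists(path)) stopf("marker file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stopf("marker file %s is empty (expected a header)", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, MARKER_COLUMNS))
    stopf("bad marker header in %s: expected '%s'", path,
          paste(MARKER_COLUMNS, collapse = "\t"))
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 5L)
      stopf("%s line %d: expected 5 tab-separated fields, got %d",
            path, i + 1L, length(f))
    xy <- suppressWarnings(as.numeric(f[2:3]))
    if (anyNA(xy) || any(xy != floor(xy)))
      stopf("%s line %d: x/y must be integers, got '%s', '%s'",
            path, i + 1L, f[2], f[3])
    data.frame(image_id = f[1], x = as.integer(xy[1]), y = as.integer(xy[2]),
               label = f[4], dataset_tag = f[5])
  })
  tab <- if (length(rows)) do.call(rbind, rows) else empty_marker_table()
  assert_labels(tab$label, taxonomy)
  if (!is.null(image_size)) {
    bad <- tab$x < 0 | tab$x >= image_size[1] | tab$y < 0 | tab$y >= image_size[2]
    if (any(bad))
      stopf("%d marker(s) outside the %dx%d image bounds (first at row %d)",
            sum(bad), image_size[1], image_size[2], which(bad)[1] + 1L)
  }
  as_marker_table(tab, validate = FALSE)
}

#' @rdname read_markers
#' @param table a `marker_table` (or data frame with the marker columns).
#' @export
write_markers <- function(table, path) {
  stopifnot(all(MARKER_COLUMNS %in% names(table)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(MARKER_COLUMNS, collapse = "\t"), con)
  if (nrow(table))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%s", table$image_id, table$x,
                       table$y, table$label, table$dataset_tag), con)
  invisible(path)
}

reflect_index <- function(i, n) {
  # mirror without repeating the border pixel: ... 3 2 | 1 2 3 ... n | n-1
  i <- ifelse(i < 1L, 2L - i, i)
  ifelse(i > n, 2L * n - i, i)
}

#' Crop labelled sub-images around markers
#'
#' Cuts a `size x size` patch centred on every marker (`size` must be odd
#' so the marker is the centre pixel).  Markers within `size %/% 2` pixels
#' of a border are handled per `edge_policy`: `"reflect"` (default) mirrors
#' the image across its border so every marker yields a full-size patch;
#' `"skip"` drops such markers and reports them.
#'
#' @param image `h x w x 3` array or `h x w` matrix, 8-bit valued.
#' @param markers a `marker_table` referring to this image.
#' @param size odd patch edge length.
#' @param edge_policy `"reflect"` or `"skip"`.
#' @return a `subimage_set`; the indices of skipped markers are attached as
#'   attribute `skipped`.
#' @export
crop_subimages <- function(image, markers, size = 201L,
                           edge_policy = c("reflect", "skip")) {
  edge_policy <- match.arg(edge_policy)
  if (size %% 2L == 0L) stopf("patch size must be odd, got %d", size)
  dims <- dim(image)
  h <- dims[1]; w <- dims[2]
  half <- (size - 1L) %/% 2L
  if (any(markers$x < 0 | markers$x >= w | markers$y < 0 | markers$y >= h))
    stopf("marker positions outside the %dx%d image", w, h)
  rows_c <- markers$y + 1L  # 0-based marker coords -> 1-based matrix indices
  cols_c <- markers$x + 1L
  near_edge <- rows_c - half < 1L | rows_c + half > h |
    cols_c - half < 1L | cols_c + half > w
  keep <- if (edge_policy == "skip") which(!near_edge) else seq_len(nrow(markers))
  skipped <- setdiff(seq_len(nrow(markers)), keep)
  if (length(skipped))
    message(sprintf("crop_subimages: skipped %d marker(s) within %d px of a border",
                    length(skipped), half))
  patches <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    ri <- reflect_index((rows_c[i] - half):(rows_c[i] + half), h)
    ci <- reflect_index((cols_c[i] - half):(cols_c[i] + half), w)
    patches[[j]] <- if (length(dims) == 3L) image[ri, ci, , drop = FALSE]
      else image[ri, ci, drop = FALSE]
  }
  info <- data.frame(label = markers$label[keep],
                     decay = NA_real_,
                     dataset_tag = markers$dataset_tag[keep],
                     image_id = markers$image_id[keep],
                     x = markers$x[keep], y = markers$y[keep])
  out <- new_subimage_set(patches, info)
  attr(out, "skipped") <- skipped
  out
}

#' Stratified split into model-fitting and optimization sets
#'
#' Randomly splits records per class: `floor(fraction * n)` of each class
#' (never all of it, so at least one record per class is held out when the
#' class has two or more) go to the model-fitting set, the rest to the
#' optimization set.  Classes with fewer than 2 records stay whole in the
#' fitting set with a warning.  The same seed reproduces the same split.
#'
#' @param x a `subimage_set`, or a vector of class labels.
#' @param fraction model-fitting share, in (0, 1).
#' @param rng_seed integer seed.
#' @return for a `subimage_set`, `list(model =, optimization =)` of
#'   `subimage_set`s; for a label vector, the same structure holding index
#'   vectors.
#' @export
split_train_opt <- function(x, fraction = 0.75, rng_seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stopf("fraction must lie in (0, 1)")
  labels <- if (inherits(x, "subimage_set")) x$info$label else as.character(x)
  idx_fit <- with_seed(rng_seed, {
    unlist(lapply(split(seq_along(labels), labels), function(idx) {
      n <- length(idx)
      if (n < 2L) {
        warnf("class %s has %d record(s); kept whole in the fitting set",
              labels[idx[1]], n)
        return(idx)
      }
      n_fit <- min(max(1L, floor(fraction * n)), n - 1L)
      sample(idx, n_fit)
    }), use.names = FALSE)
  })
  idx_fit <- sort(idx_fit)
  idx_opt <- setdiff(seq_along(labels), idx_fit)
  if (inherits(x, "subimage_set"))
    list(model = x[idx_fit], optimization = x[idx_opt])
  else list(model = idx_fit, optimization = idx_opt)
}

#' Temporal and categorical pooling schemes
#'
#' Categorical pooling merges morphologically near-identical classes into
#' one (by default the whitefly pair BEMITA + TRIAVA into BEM-TRI);
#' temporal pooling merges the fresh and aged dataset tags (by default
#' Lab0d + Lab7d) into one tag.  Pooling relabels records and never changes
#' their number.
#'
#' @param categorical `TRUE` for the default whitefly map, a named
#'   character vector `c(old = new, ...)` for a custom map, or `FALSE` for
#'   no categorical pooling.  Labels missing from a custom map stay fixed.
#' @param temporal merge dataset tags?
#' @param tags dataset tags to merge.
#' @param merged_tag replacement tag.
#' @param taxonomy labels over which the categorical map must be total.
#' @return a `pooling_scheme`.
#' @export
pooling_scheme <- function(categorical = TRUE, temporal = FALSE,
                           tags = c("Lab0d", "Lab7d"),
                           merged_tag = "Lab0d-7d",
                           taxonomy = trap_taxonomy()) {
  map <- stats::setNames(taxonomy, taxonomy)
  if (isTRUE(categorical)) {
    map[c("BEMITA", "TRIAVA")] <- "BEM-TRI"
  } else if (is.character(categorical)) {
    assert_labels(names(categorical), taxonomy, "map domain label")
    map[names(categorical)] <- categorical
  }
  # idempotence: pooled output labels map to themselves, so applying a
  # scheme to already-pooled records is a no-op rather than an error
  for (v in setdiff(unname(map), names(map))) map[v] <- v
  structure(list(map = map, temporal = isTRUE(temporal), tags = tags,
                 merged_tag = merged_tag),
            class = "pooling_scheme")
}

#' Apply a pooling scheme
#'
#' @param x a character vector of labels, a `marker_table`, or a
#'   `subimage_set`.
#' @param scheme a [pooling_scheme()].
#' @return `x` with labels (and, for temporal pooling, dataset tags)
#'   relabelled; record counts are unchanged.
#' @export
apply_pooling <- function(x, scheme) {
  stopifnot(inherits(scheme, "pooling_scheme"))
  pool_labels <- function(labels) {
    out <- scheme$map[labels]
    if (anyNA(out))
      stopf("label(s) outside the pooling scheme domain: %s",
            paste(unique(labels[is.na(out)]), collapse = ", "))
    unname(out)
  }
  pool_tags <- function(tags) {
    if (scheme$temporal) ifelse(tags %in% scheme$tags, scheme$merged_tag, tags)
    else tags
  }
  if (is.character(x)) return(pool_labels(x))
  if (inherits(x, "subimage_set")) {
    x$info$label <- pool_labels(x$info$label)
    x$info$dataset_tag <- pool_tags(x$info$dataset_tag)
    return(x)
  }
  if (is.data.frame(x) && all(c("label", "dataset_tag") %in% names(x))) {
    x$label <- pool_labels(x$label)
    x$dataset_tag <- pool_tags(x$dataset_tag)
    return(x)
  }
  stopf("apply_pooling() supports label vectors, marker tables and subimage sets")
}

#' Pooled taxonomy implied by a scheme
#' @param scheme a [pooling_scheme()].
#' @return character vector of pooled class labels, in first-appearance
#'   order of the source taxonomy.
#' @export
pooled_taxonomy <- function(scheme) unique(unname(scheme$map))

#' Read and write trap-scene images
#'
#' Scenes are 8-bit RGB images; PNG is the native format (TIFF reading is
#' supported when the tiff package is installed).
#'
#' @param path image path.
#' @return `read_scene()` returns an `h x w x 3` array valued 0--255.
#' @export
read_scene <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopf("reading TIFF requires the tiff package")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

#' @rdname read_scene
#' @param image `h x w x 3` array valued 0--255.
#' @export
write_scene <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}
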