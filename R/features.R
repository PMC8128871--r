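#' Convert an 8-bit RGB image to a working colour space
#'
#' Greyscale conversion uses the ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114) and rounds to 8-bit.  HSV conversion maps hue,
#' saturation and value each onto 0--255 so all channels share the 8-bit
#' range the descriptor stage expects.
#'
#' @param image numeric array `h x w x 3` with values in 0--255.
#' @param space one of `"greyscale"`, `"rgb"`, `"hsv"`.
#' @return for `"greyscale"` an `h x w` matrix; otherwise an `h x w x 3`
#'   array, all 8-bit valued.
#' @export
convert_colour <- function(image, space = c("greyscale", "rgb", "hsv")) {
  space <- match.arg(space)
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stopf("convert_colour() expects an h x w x 3 array, got dims %s",
          paste(dim(image), collapse = "x"))
  if (min(image) < 0 || max(image) > 255)
    stopf("pixel values must lie in 0..255")
  switch(space,
    rgb = image,
    greyscale = round(0.299 * image[, , 1] + 0.587 * image[, , 2] +
                        0.114 * image[, , 3]),
    hsv = {
      d <- dim(image)
      m <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                 as.vector(image[, , 3]))
      hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
      out <- array(0, dim = d)
      out[, , 1] <- round(hsv[1, ] * 255)
      out[, , 2] <- round(hsv[2, ] * 255)
      out[, , 3] <- round(hsv[3, ] * 255)
      out
    })
}

#' SIFT detector and descriptor parameters
#'
#' @param peak_threshold minimum absolute difference-of-Gaussians response
#'   (images scaled to \[0,1\]) for a keypoint; smaller finds more blobs.
#' @param edge_threshold Hessian trace/determinant ratio bound rejecting
#'   edge-like responses (the classical `r` with threshold `(r+1)^2/r`).
#' @param n_levels difference-of-Gaussians scales sampled per octave.
#' @param dense_fallback if `TRUE`, a patch where the blob detector finds
#'   nothing is re-described on a regular grid (orientation 0) so it still
#'   contributes descriptors; a truly constant patch stays empty either way.
#' @param dense_step,dense_sigma grid spacing and scale of the fallback.
#' @return a list of class `sift_params`.
#' @export
sift_params <- function(peak_threshold = 0.003, edge_threshold = 10,
                        n_levels = 3, dense_fallback = FALSE,
                        dense_step = 12, dense_sigma = 2.0) {
  stopifnot(peak_threshold > 0, edge_threshold > 1, n_levels >= 1)
  structure(list(peak_threshold = peak_threshold,
                 edge_threshold = edge_threshold,
                 n_levels = as.integer(n_levels),
                 dense_fallback = isTRUE(dense_fallback),
                 dense_step = as.integer(dense_step),
                 dense_sigma = dense_sigma),
            class = "sift_params")
}

new_descriptor_set <- function(descriptors, keypoints) {
  stopifnot(ncol(descriptors) == 128L, nrow(descriptors) == nrow(keypoints))
  structure(list(descriptors = descriptors, keypoints = keypoints),
            class = "descriptor_set")
}

#' Extract SIFT descriptors from an image
#'
#' SIFT is defined on scalar images, so multi-channel inputs are handled by
#' running the detector independently on every channel and pooling the
#' resulting 128-dimensional descriptors into one set, each keypoint tagged
#' with its channel of origin.  An empty set is a valid result (e.g. for a
#' constant patch).
#'
#' @param image `h x w` matrix (single channel) or `h x w x c` array, 8-bit
#'   valued.
#' @param params a [sift_params()] object.
#' @return a `descriptor_set`: `descriptors` (`n x 128` matrix, entries in
#'   0--255) and `keypoints` (data frame with 0-based `x`, `y` plus `scale`,
#'   `orientation`, `channel`).
#' @export
extract_descriptors <- function(image, params = sift_params()) {
  stopifnot(inherits(params, "sift_params"))
  channels <- if (length(dim(image)) == 3L) {
    lapply(seq_len(dim(image)[3]), function(k) image[, , k])
  } else if (is.matrix(image)) list(image) else
    stopf("image must be a matrix or a 3-d array")

  one_channel <- function(ch, k) {
    res <- sift_detect_cpp(ch / 255, params$peak_threshold,
                           params$edge_threshold, params$n_levels)
    if (nrow(res$descriptors) == 0L && params$dense_fallback)
      res <- sift_dense_cpp(ch / 255, params$dense_step, params$dense_sigma)
    kp <- as.data.frame(res$keypoints)
    kp$channel <- rep.int(k, nrow(kp))
    list(desc = res$descriptors, kp = kp)
  }
  parts <- Map(one_channel, channels, seq_along(channels))
  desc <- do.call(rbind, lapply(parts, `[[`, "desc"))
  kp <- do.call(rbind, lapply(parts, `[[`, "kp"))
  if (is.null(desc)) desc <- matrix(numeric(0), 0, 128)
  rownames(kp) <- NULL
  new_descriptor_set(desc, kp)
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat(sprintf("<descriptor_set: %d SIFT descriptors (128-d), %d channel(s)>\n",
              nrow(x$descriptors),
              length(unique(x$keypoints$channel))))
  invisible(x)
}

#' Persist / load a descriptor set as delimited text
#'
#' Descriptors go to `<prefix>.tsv` (one 128-column row per keypoint) and
#' the keypoint listing (x, y, scale, orientation, channel) to
#' `<prefix>-keypoints.tsv`.
#'
#' @param descriptors a `descriptor_set`.
#' @param prefix file path without extension.
#' @export
write_descriptors <- function(descriptors, prefix) {
  stopifnot(inherits(descriptors, "descriptor_set"))
  utils::write.table(descriptors$descriptors, paste0(prefix, ".tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(descriptors$keypoints, paste0(prefix, "-keypoints.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(prefix) {
  desc <- as.matrix(utils::read.delim(paste0(prefix, ".tsv"), header = FALSE))
  dimnames(desc) <- NULL
  if (length(desc) == 0L) desc <- matrix(numeric(0), 0, 128)
  kp <- utils::read.delim(paste0(prefix, "-keypoints.tsv"))
  new_descriptor_set(desc, kp)
}
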