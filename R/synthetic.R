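# Synthetic trap imagery.  The generator does not aim at photorealism: it
# reproduces the statistical structure the analysis depends on -- five
# classes with distinct size/texture signatures, one near-identical whitefly
# pair separated only by wing colour, a scalar "decay" that fades insects
# towards the yellow background the way week-old catches fade, and clutter
# objects that belong to no trained class.

hsv255_to_rgb <- function(hsv) {
  stopifnot(length(hsv) == 3, all(hsv >= 0 & hsv <= 255))
  as.numeric(grDevices::col2rgb(grDevices::hsv(hsv[1] / 255, hsv[2] / 255,
                                               hsv[3] / 255)))
}

# how strongly decay = 1 fades each layer towards the background
DECAY_FADE_WING <- 0.95
DECAY_FADE_BODY <- 0.55

#' Synthetic class appearance specification
#'
#' @param label class name (one of the taxonomy labels or `CLUTTER`).
#' @param shape_params list with `body_axes` (ellipse semi-axes, px),
#'   `wing_count`, `antenna` (flag).
#' @param colour_params list with `body`, `wing` HSV triplets (0--255) and
#'   `wing_opacity` in \[0,1\].
#' @param texture_params list with `speckle_density` (blobs per 100 px^2 of
#'   body area) and `blob_scale` (px).
#' @return a `class_spec`.
#' @export
class_spec <- function(label, shape_params, colour_params, texture_params) {
  assert_labels(label, renderable_labels())
  stopifnot(length(shape_params$body_axes) == 2,
            all(shape_params$body_axes >= 0),
            is_count(shape_params$wing_count),
            is.logical(shape_params$antenna))
  for (f in c("body", "wing"))
    if (any(colour_params[[f]] < 0 | colour_params[[f]] > 255))
      stopf("colour values must lie in 0..255 (%s of %s)", f, label)
  stopifnot(colour_params$wing_opacity >= 0, colour_params$wing_opacity <= 1,
            texture_params$speckle_density >= 0, texture_params$blob_scale > 0)
  structure(list(label = label, shape_params = shape_params,
                 colour_params = colour_params, texture_params = texture_params),
            class = "class_spec")
}

#' Default class specifications
#'
#' BEMITA and TRIAVA share identical shape and texture parameters and differ
#' only in wing colour/opacity: BEMITA wings are brighter than the yellow
#' background in luma, TRIAVA wings darker, so the pair is separable in any
#' colour space while fresh but collapses onto the shared dark body as the
#' wings fade with decay -- the generator's built-in hard pair.
#'
#' @return named list of [class_spec()] objects.
#' @export
default_class_specs <- function() {
  whitefly_shape <- list(body_axes = c(22, 13), wing_count = 2L, antenna = FALSE)
  whitefly_texture <- list(speckle_density = 6, blob_scale = 1.5)
  whitefly_body <- c(18, 200, 95)
  list(
    BEMITA = class_spec("BEMITA", whitefly_shape,
                        list(body = whitefly_body, wing = c(32, 25, 255),
                             wing_opacity = 0.95),
                        whitefly_texture),
    TRIAVA = class_spec("TRIAVA", whitefly_shape,
                        list(body = whitefly_body, wing = c(120, 90, 140),
                             wing_opacity = 0.85),
                        whitefly_texture),
    ENCAFO = class_spec("ENCAFO",
                        list(body_axes = c(11, 7), wing_count = 2L, antenna = FALSE),
                        list(body = c(170, 220, 70), wing = c(20, 40, 220),
                             wing_opacity = 0.7),
                        list(speckle_density = 12, blob_scale = 1.0)),
    MACRPY = class_spec("MACRPY",
                        list(body_axes = c(32, 9), wing_count = 2L, antenna = TRUE),
                        list(body = c(78, 210, 160), wing = c(70, 80, 190),
                             wing_opacity = 0.6),
                        list(speckle_density = 3.5, blob_scale = 2.5)),
    BKGRND = class_spec("BKGRND",
                        list(body_axes = c(0, 0), wing_count = 0L, antenna = FALSE),
                        list(body = c(30, 205, 235), wing = c(30, 205, 235),
                             wing_opacity = 0),
                        list(speckle_density = 0.35, blob_scale = 2.0)),
    CLUTTER = class_spec("CLUTTER",
                         list(body_axes = c(14, 10), wing_count = 0L, antenna = FALSE),
                         list(body = c(8, 150, 120), wing = c(8, 150, 120),
                              wing_opacity = 0),
                         list(speckle_density = 4, blob_scale = 2.0))
  )
}

#' Default yellow trap background
#'
#' @param hsv background HSV triplet on the 0--255 scale.
#' @param noise_sd per-pixel luminance noise standard deviation.
#' @param speckle_density darker dots per 100 px^2 (adhesive/texture grain,
#'   which also gives background patches descriptors of their own).
#' @return a `trap_background` list.
#' @export
trap_background <- function(hsv = c(30, 205, 235), noise_sd = 2,
                            speckle_density = 0.2) {
  structure(list(hsv = hsv, rgb = hsv255_to_rgb(hsv), noise_sd = noise_sd,
                 speckle_density = speckle_density),
            class = "trap_background")
}

# linear pixel indices of a disc, clipped to an h x w matrix
disc_pixels <- function(cx, cy, r, h, w) {
  x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(integer(0))
  xs <- x0:x1; ys <- y0:y1
  sel <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
  (rep(xs, each = length(ys))[sel] - 1L) * h + rep(ys, length(xs))[sel]
}

# stamp many discs at once; per-channel delta = shade * channel_scale,
# overlapping discs accumulate
stamp_discs <- function(ch, cx, cy, r, shade, channel_scale = c(1, 1, 1)) {
  h <- nrow(ch[[1]]); w <- ncol(ch[[1]])
  px <- lapply(seq_along(cx), function(i) disc_pixels(cx[i], cy[i], r[i], h, w))
  idx <- unlist(px)
  if (!length(idx)) return(ch)
  per <- rep(shade, lengths(px))
  agg <- rowsum(per, idx)
  at <- as.integer(rownames(agg))
  for (k in 1:3) {
    v <- ch[[k]]
    nv <- v[at] + agg[, 1] * channel_scale[k]
    nv[nv < 0] <- 0; nv[nv > 255] <- 255
    v[at] <- nv
    ch[[k]] <- v
  }
  ch
}

# textured background; consumes the active RNG stream
make_background <- function(width, height, background) {
  ch <- lapply(background$rgb, function(v) matrix(v, height, width))
  noise <- matrix(stats::rnorm(width * height, 0, background$noise_sd), height, width)
  for (k in 1:3) {
    v <- ch[[k]] + noise
    v[v < 0] <- 0; v[v > 255] <- 255
    ch[[k]] <- v
  }
  n_dots <- round(background$speckle_density * width * height / 100)
  if (n_dots > 0) {
    cx <- stats::runif(n_dots, 1, width)
    cy <- stats::runif(n_dots, 1, height)
    r <- stats::runif(n_dots, 1, 2.5)
    shade <- stats::runif(n_dots, 25, 70)
    ch <- stamp_discs(ch, cx, cy, r, -shade, c(0.6, 0.8, 1.0))
  }
  ch
}

rot_ellipse_mask <- function(X, Y, cx, cy, a, b, theta) {
  if (a <= 0 || b <= 0) return(matrix(FALSE, nrow(X), ncol(X)))
  dx <- X - cx; dy <- Y - cy
  u <- (cos(theta) * dx + sin(theta) * dy) / a
  v <- (-sin(theta) * dx + cos(theta) * dy) / b
  u^2 + v^2 <= 1
}

draw_segment_mask <- function(mask, x0, y0, x1, y1, halfwidth = 1) {
  h <- nrow(mask); w <- ncol(mask)
  n <- max(2L, ceiling(2 * sqrt((x1 - x0)^2 + (y1 - y0)^2)))
  ts <- seq(0, 1, length.out = n)
  xs <- round(x0 + ts * (x1 - x0)); ys <- round(y0 + ts * (y1 - y0))
  off <- expand.grid(dx = -halfwidth:halfwidth, dy = -halfwidth:halfwidth)
  off <- off[off$dx^2 + off$dy^2 <= halfwidth^2, ]
  for (i in seq_len(nrow(off))) {
    px <- xs + off$dx[i]; py <- ys + off$dy[i]
    keep <- px >= 1 & px <= w & py >= 1 & py <= h
    mask[cbind(py[keep], px[keep])] <- TRUE
  }
  mask
}

# Draw one insect onto channel matrices at (cx, cy) (1-based matrix coords).
# Consumes the active RNG stream for pose and texture.  Returns the channels
# and the geometric foreground mask (decay-independent).
render_object <- function(ch, spec, decay, cx, cy) {
  h <- nrow(ch[[1]]); w <- ncol(ch[[1]])
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)
  shp <- spec$shape_params; col <- spec$colour_params; tex <- spec$texture_params
  if (all(shp$body_axes <= 0))
    return(list(ch = ch, mask = matrix(FALSE, h, w)))

  theta <- stats::runif(1, 0, 2 * pi)
  scale <- stats::runif(1, 0.9, 1.1)
  a <- shp$body_axes[1] * scale; b <- shp$body_axes[2] * scale

  body <- rot_ellipse_mask(X, Y, cx, cy, a, b, theta)
  wings <- matrix(FALSE, h, w)
  if (shp$wing_count >= 1) {
    for (j in c(-1, 1)[seq_len(min(2L, shp$wing_count))]) {
      phi <- theta + j * 0.55
      wx <- cx - 0.55 * a * cos(phi - j * 1.1)
      wy <- cy - 0.55 * a * sin(phi - j * 1.1)
      wings <- wings | rot_ellipse_mask(X, Y, wx, wy, 0.9 * a, 0.5 * b, phi)
    }
  }
  antennae <- matrix(FALSE, h, w)
  if (isTRUE(shp$antenna)) {
    hx <- cx + a * cos(theta); hy <- cy + a * sin(theta)
    for (j in c(-1, 1)) {
      phi <- theta + j * 0.45
      antennae <- draw_segment_mask(antennae, hx, hy,
                                    hx + 1.2 * a * cos(phi),
                                    hy + 1.2 * a * sin(phi), 1)
    }
  }
  mask <- body | wings | antennae

  body_rgb <- hsv255_to_rgb(col$body)
  wing_rgb <- hsv255_to_rgb(col$wing)
  alpha_body <- 1 - decay * DECAY_FADE_BODY
  alpha_wing <- col$wing_opacity * (1 - decay * DECAY_FADE_WING)

  blend <- function(region, rgb, alpha) {
    if (!any(region) || alpha <= 0) return(invisible(NULL))
    for (k in 1:3)
      ch[[k]][region] <<- (1 - alpha) * ch[[k]][region] + alpha * rgb[k]
    invisible(NULL)
  }
  blend(wings & !body, wing_rgb, alpha_wing)
  blend(body | antennae, body_rgb, alpha_body)

  # speckle texture on body and wings, fading with the same alphas as the
  # underlying layer (same draw order for equal shapes, so the whitefly
  # pair keeps identical geometry under identical seeds)
  speckle_region <- function(region, alpha) {
    area <- sum(region)
    n_spots <- round(tex$speckle_density * area / 100)
    if (n_spots > 0 && area > 0) {
      idx <- which(region)
      pick <- idx[ceiling(stats::runif(n_spots) * length(idx))]
      py <- (pick - 1) %% h + 1; px <- (pick - 1) %/% h + 1
      shade <- stats::runif(n_spots, 40, 100) * alpha
      ch <<- stamp_discs(ch, px, py, rep(tex$blob_scale, n_spots), -shade)
    }
    invisible(NULL)
  }
  speckle_region(body, alpha_body)
  speckle_region(wings & !body, alpha_wing)
  list(ch = ch, mask = mask)
}

channels_to_array <- function(ch) {
  out <- array(0, dim = c(nrow(ch[[1]]), ncol(ch[[1]]), 3))
  for (k in 1:3) out[, , k] <- round(pmin(255, pmax(0, ch[[k]])))
  out
}

#' Render a single labelled sub-image patch
#'
#' Draws one insect of the given class, centred (with small jitter) on a
#' textured yellow background.  `decay` in \[0,1\] fades the insect towards
#' the background -- wings almost completely, the body partially -- emulating
#' the colour loss of catches that stayed a week on the trap; the
#' foreground/background contrast is monotone non-increasing in `decay`.
#' The returned mask is the geometric footprint and does not depend on
#' `decay`.  Identical `(spec, decay, rng_seed)` give bit-identical output.
#'
#' @param spec a [class_spec()]; label BKGRND yields pure background and an
#'   empty mask.
#' @param decay fraction in \[0,1\] (0 = fresh catch, 1 = week-old).
#' @param rng_seed integer seed.
#' @param size odd patch edge length in px.
#' @param background a [trap_background()].
#' @return list with `patch` (`size x size x 3` array, 0--255) and `mask`
#'   (logical `size x size` foreground matrix).
#' @export
render_insect_patch <- function(spec, decay = 0, rng_seed = 1L, size = 201L,
                                background = trap_background()) {
  stopifnot(inherits(spec, "class_spec"))
  if (!is.numeric(decay) || decay < 0 || decay > 1)
    stopf("decay must lie in [0, 1], got %s", format(decay))
  with_seed(rng_seed, {
    ch <- make_background(size, size, background)
    if (spec$label == "BKGRND") {
      list(patch = channels_to_array(ch), mask = matrix(FALSE, size, size))
    } else {
      centre <- (size + 1) / 2 + stats::rnorm(2, 0, 3)
      res <- render_object(ch, spec, decay, centre[1], centre[2])
      list(patch = channels_to_array(res$ch), mask = res$mask)
    }
  })
}

#' Scene generation configuration
#'
#' @param width,height scene size in px.
#' @param counts named vector/list of object counts per class label
#'   (`CLUTTER` objects are placed but never annotated -- non-target insects
#'   belong to the background).
#' @param decay fraction in \[0,1\] applied to every placed insect.
#' @param background a [trap_background()].
#' @param min_separation minimum pairwise distance between object centres.
#'   The default keeps individuals resolvable by a 201 px analysis window,
#'   which cannot separate same-class individuals much closer than its own
#'   radius.
#' @param border_margin minimum distance of object centres from the scene
#'   border.  The default keeps not just a full 201 px window but the whole
#'   sliding-window response plateau of an insect inside the scene, so
#'   plateau centroids are unbiased near borders.
#' @param rng_seed integer seed; identical configs give bit-identical
#'   scenes.
#' @return a `scene_config`.
#' @export
scene_config <- function(width = 1400L, height = 900L, counts = c(TRIAVA = 10),
                         decay = 0, background = trap_background(),
                         min_separation = 170, border_margin = 200,
                         rng_seed = 1L) {
  counts <- unlist(counts)
  if (length(counts)) assert_labels(names(counts), renderable_labels())
  stopifnot(all(counts >= 0), min_separation >= 0, decay >= 0, decay <= 1,
            width >= 1, height >= 1)
  structure(list(width = as.integer(width), height = as.integer(height),
                 counts = counts, decay = decay, background = background,
                 min_separation = min_separation,
                 border_margin = border_margin,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

#' Generate a full synthetic trap scene with ground-truth markers
#'
#' Places the requested objects at mutually separated random positions on a
#' textured yellow background and returns the scene together with its
#' marker table (one row per placed insect, at the object centre, 0-based
#' x = column / y = row coordinates; clutter objects are drawn but not
#' listed).
#'
#' @param config a [scene_config()].
#' @param specs class specifications, defaulting to [default_class_specs()].
#' @param dataset_tag tag stored in the marker table.
#' @return list with `image` (`height x width x 3` array), `markers` (a
#'   marker-table data frame), and `clutter` (placed clutter positions).
#' @export
generate_trap_scene <- function(config, specs = default_class_specs(),
                                dataset_tag = "synthetic") {
  stopifnot(inherits(config, "scene_config"))
  counts <- config$counts[config$counts > 0]
  with_seed(config$rng_seed, {
    ch <- make_background(config$width, config$height, config$background)
    placed <- matrix(numeric(0), 0, 2)
    rows <- list(); clutter <- list()
    m <- config$border_margin
    if (length(counts) &&
        (config$width < 2 * m + 1 || config$height < 2 * m + 1))
      stopf("scene %dx%d too small for border margin %d",
            config$width, config$height, m)
    labs <- rep(names(counts), times = counts)
    for (lab in labs)
      if (is.null(specs[[lab]])) stopf("no class_spec for label %s", lab)
    # place all centres first; sequential rejection sampling can paint
    # itself into a corner, so restart the whole layout when it does
    if (length(labs)) {
      done <- FALSE
      for (restart in seq_len(50L)) {
        placed <- matrix(numeric(0), 0, 2)
        stuck <- FALSE
        for (j in seq_along(labs)) {
          ok <- FALSE
          for (try in seq_len(200L)) {
            px <- stats::runif(1, m + 1, config$width - m)
            py <- stats::runif(1, m + 1, config$height - m)
            if (nrow(placed) == 0L ||
                min(sqrt((placed[, 1] - px)^2 + (placed[, 2] - py)^2)) >=
                  config$min_separation) { ok <- TRUE; break }
          }
          if (!ok) { stuck_lab <- labs[j]; stuck <- TRUE; break }
          placed <- rbind(placed, c(px, py))
        }
        if (!stuck) { done <- TRUE; break }
      }
      if (!done)
        stopf("could not place all objects (stuck at class %s) at min_separation %g",
              stuck_lab, config$min_separation)
      for (j in seq_along(labs)) {
        lab <- labs[j]
        res <- render_object(ch, specs[[lab]], config$decay,
                             placed[j, 1], placed[j, 2])
        ch <- res$ch
        entry <- data.frame(image_id = "scene", x = round(placed[j, 1]) - 1L,
                            y = round(placed[j, 2]) - 1L, label = lab,
                            dataset_tag = dataset_tag)
        if (lab == "CLUTTER") clutter[[length(clutter) + 1L]] <- entry
        else rows[[length(rows) + 1L]] <- entry
      }
    }
    markers <- if (length(rows)) do.call(rbind, rows) else empty_marker_table()
    rownames(markers) <- NULL
    clutter <- if (length(clutter)) do.call(rbind, clutter) else empty_marker_table()
    list(image = channels_to_array(ch),
         markers = as_marker_table(markers, validate = FALSE),
         clutter = clutter)
  })
}

#' Generate a labelled sub-image dataset
#'
#' Renders `n` patches per class, each with a decay value drawn from the
#' given decay distribution, emulating the fresh (Lab0d-style) and aged
#' (Lab7d-style) laboratory patch sets.
#'
#' @param counts named vector of patches per class label.
#' @param decay_levels,decay_probs the decay distribution (levels sampled
#'   with these probabilities; default all-fresh).
#' @param rng_seed integer seed.
#' @param dataset_tag tag carried by every record.
#' @param size odd patch size.
#' @param specs class specifications.
#' @param background a [trap_background()].
#' @return a `subimage_set`: `patches` (list of arrays) and `info` (data
#'   frame with label, decay, dataset_tag, image_id, x, y).
#' @export
generate_dataset <- function(counts, decay_levels = 0, decay_probs = 1,
                             rng_seed = 1L, dataset_tag = "synthetic",
                             size = 201L, specs = default_class_specs(),
                             background = trap_background()) {
  counts <- unlist(counts)
  assert_labels(names(counts), renderable_labels())
  stopifnot(all(counts >= 0), length(decay_levels) == length(decay_probs),
            all(decay_probs >= 0), sum(decay_probs) > 0)
  decay_probs <- decay_probs / sum(decay_probs)
  labels <- rep(names(counts), times = counts)
  n <- length(labels)
  with_seed(rng_seed, {
    decays <- if (length(decay_levels) == 1L) rep(decay_levels, n)
      else sample(decay_levels, n, replace = TRUE, prob = decay_probs)
    seeds <- sample.int(.Machine$integer.max - 1L, n, replace = TRUE)
    patches <- vector("list", n)
    for (i in seq_len(n))
      patches[[i]] <- render_insect_patch(specs[[labels[i]]], decays[i],
                                          seeds[i], size, background)$patch
    centre <- (size - 1L) %/% 2L
    info <- data.frame(label = labels, decay = decays,
                       dataset_tag = dataset_tag,
                       image_id = sprintf("%s-%05d", dataset_tag, seq_len(n)),
                       x = centre, y = centre)
    new_subimage_set(patches, info)
  })
}

new_subimage_set <- function(patches, info) {
  stopifnot(length(patches) == nrow(info))
  structure(list(patches = patches, info = info), class = "subimage_set")
}

#' @export
print.subimage_set <- function(x, ...) {
  tab <- table(x$info$label)
  cat(sprintf("<subimage_set: %d patches (%s)>\n", length(x$patches),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
`[.subimage_set` <- function(x, i) {
  new_subimage_set(x$patches[i], x$info[i, , drop = FALSE])
}

#' Combine sub-image sets
#' @param ... `subimage_set` objects.
#' @return the concatenated `subimage_set`.
#' @export
c.subimage_set <- function(...) {
  sets <- list(...)
  info <- do.call(rbind, lapply(sets, `[[`, "info"))
  rownames(info) <- NULL
  new_subimage_set(do.call(c, lapply(sets, `[[`, "patches")), info)
}

#' Read a scene configuration from a YAML file
#'
#' Keys mirror the [scene_config()] fields (`width`, `height`, `counts`,
#' `decay`, `min_separation`, `border_margin`, `rng_seed`, and optionally
#' `background: {hsv, noise_sd, speckle_density}`).
#'
#' @param path YAML file path.
#' @return a `scene_config`.
#' @export
read_scene_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bg <- if (is.null(cfg$background)) trap_background() else
    trap_background(hsv = as.numeric(cfg$background$hsv %||% c(30, 205, 235)),
                    noise_sd = cfg$background$noise_sd %||% 2,
                    speckle_density = cfg$background$speckle_density %||% 0.2)
  scene_config(width = cfg$width %||% 1400L,
               height = cfg$height %||% 900L,
               counts = unlist(cfg$counts) %||% c(),
               decay = cfg$decay %||% 0,
               background = bg,
               min_separation = cfg$min_separation %||% 170,
               border_margin = cfg$border_margin %||% 200,
               rng_seed = cfg$rng_seed %||% 1L)
}
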