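fake_map <- function(df, stride = 25L, window = 201L) {
  df$score <- df$score %||% 1
  class(df) <- c("category_map", "data.frame")
  attr(df, "stride") <- stride
  attr(df, "window") <- window
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the scan grid has the analytic cell count", {
  m <- tiny_model()
  sc <- generate_trap_scene(scene_config(width = 320, height = 280,
                                         counts = c(), border_margin = 110,
                                         rng_seed = 3))
  map <- scan_scene(sc$image, m, window = 201, stride = 25)
  expect_equal(nrow(map),
               (floor((320 - 201) / 25) + 1) * (floor((280 - 201) / 25) + 1))
  # stride spanning the whole leftover: exactly one cell
  one <- scan_scene(sc$image, m, window = 201, stride = 320 - 201 + 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$x, 100); expect_equal(one$y, 100)
  expect_error(scan_scene(sc$image[1:100, , ], m), "smaller than")
})

test_that("an empty scene yields no detections and a background-dominated map", {
  # the tiny fixture model leaves the strict all-background claim to the
  # acceptance-scale run; here: overwhelmingly background, and no stray
  # cell survives the support filter
  m <- tiny_model()
  sc <- generate_trap_scene(scene_config(width = 430, height = 380,
                                         counts = c(), border_margin = 110,
                                         rng_seed = 11))
  map <- scan_scene(sc$image, m, stride = 50)
  expect_gte(mean(map$label == "BKGRND"), 0.9)
  expect_equal(nrow(detect_insects(sc$image, m, stride = 50)), 0)
})

test_that("scanning the window centred on a patch reproduces the patch prediction", {
  m <- tiny_model()
  te <- tiny_test_set()[1:5]
  patch_pred <- predict_bovw(m, te)$label
  for (i in 1:5) {
    map <- scan_scene(te$patches[[i]], m, window = 201, stride = 1)
    expect_equal(nrow(map), 1)
    expect_equal(map$label, patch_pred[i])
  }
})

test_that("single-cell and nearby-cell suppression behave as specified", {
  map1 <- fake_map(data.frame(x = c(100, 150), y = c(100, 100),
                              label = c("TRIAVA", "BKGRND"),
                              score = c(2, 5)))
  det <- extract_detections(map1, refine = "none", cross_class = FALSE,
                            suppression_radius = 30)
  expect_equal(nrow(det), 1)
  expect_equal(det$label, "TRIAVA")
  expect_equal(det$x, 100)

  map2 <- fake_map(data.frame(x = c(100, 105), y = c(100, 100),
                              label = "TRIAVA", score = c(1, 3)))
  det2 <- extract_detections(map2, refine = "none", cross_class = FALSE,
                             suppression_radius = 30)
  expect_equal(nrow(det2), 1)
  expect_equal(det2$x, 105)   # the higher-scoring cell wins
})

test_that("greedy per-class suppression matches a brute-force oracle", {
  # oracle: repeatedly keep the globally best remaining cell of each class
  # (ties by y then x) and delete its same-class neighbours within radius
  nms_oracle <- function(df, radius) {
    kept <- integer(0)
    left <- order(-df$score, df$y, df$x)
    while (length(left)) {
      i <- left[1]
      kept <- c(kept, i)
      left <- left[!(df$label[left] == df$label[i] &
                       sqrt((df$x[left] - df$x[i])^2 +
                              (df$y[left] - df$y[i])^2) <= radius)]
    }
    df[sort(kept), ]
  }
  for (seed in 1:30) {
    df <- with_seed_local(seed, data.frame(
      x = sample(0:300, 18, TRUE), y = sample(0:300, 18, TRUE),
      label = sample(c("A", "B"), 18, TRUE),
      score = round(stats::runif(18), 3)))
    got <- extract_detections(fake_map(df), min_score = -Inf, refine = "none",
                              cross_class = FALSE, suppression_radius = 60,
                              background_label = "ZZZ")
    want <- nms_oracle(df, 60)
    got <- got[order(got$x, got$y), ]
    want <- want[order(want$x, want$y), c("x", "y", "label", "score")]
    expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
})

test_that("detection matching is one-to-one and counts leftovers", {
  markers <- as_marker_table <- data.frame(
    image_id = "s", x = c(100L, 300L, 500L), y = c(100L, 100L, 100L),
    label = c("TRIAVA", "TRIAVA", "MACRPY"), dataset_tag = "synthetic")
  det_same <- data.frame(x = markers$x, y = markers$y, label = markers$label,
                         score = 1)
  res <- match_detections(det_same, markers, 30)
  expect_equal(res$tp, 3); expect_equal(res$fp, 0); expect_equal(res$fn, 0)
  expect_equal(res$recall, 1); expect_equal(res$precision, 1)

  res_none <- match_detections(det_same[0, ], markers, 30)
  expect_equal(res_none$fn, 3); expect_equal(res_none$tp, 0)

  # wrong class within tolerance is no match; pooling can repair it
  det_cls <- data.frame(x = 100, y = 100, label = "BEMITA", score = 1)
  expect_equal(match_detections(det_cls, markers, 30)$tp, 0)
  expect_equal(match_detections(det_cls, markers, 30,
                                scheme = pooling_scheme(categorical = TRUE))$tp, 1)
})

test_that("greedy matching equals optimal bipartite matching on small instances", {
  # oracle: maximum matching count by exhaustive permutation
  optimal_count <- function(det, mar, tol) {
    nd <- nrow(det); nm <- nrow(mar)
    ok <- outer(seq_len(nd), seq_len(nm), function(i, j)
      det$label[i] == mar$label[j] &
        sqrt((det$x[i] - mar$x[j])^2 + (det$y[i] - mar$y[j])^2) <= tol)
    best <- 0
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (p in perms(seq_len(nm))) {
      cnt <- sum(vapply(seq_len(min(nd, nm)), function(i) ok[i, p[i]], logical(1)))
      best <- max(best, cnt)
    }
    best
  }
  for (seed in 1:12) {
    n <- 5
    det <- with_seed_local(seed, data.frame(
      x = sample(0:120, n, TRUE), y = sample(0:120, n, TRUE),
      label = sample(c("A", "B"), n, TRUE), score = 1))
    mar <- with_seed_local(seed + 100, data.frame(
      image_id = "s", x = sample(0:120, n, TRUE), y = sample(0:120, n, TRUE),
      label = sample(c("A", "B"), n, TRUE), dataset_tag = "synthetic"))
    got <- match_detections(det, mar, 60)$tp
    expect_equal(got, optimal_count(det, mar, 60))
  }
})

test_that("category maps export to text and overlay files", {
  map <- fake_map(data.frame(x = c(100, 125), y = c(100, 100),
                             label = c("TRIAVA", "BKGRND"), score = c(1, 2)))
  tmp <- withr::local_tempdir()
  write_category_map(map, file.path(tmp, "map.tsv"))
  back <- utils::read.delim(file.path(tmp, "map.tsv"))
  expect_equal(back$label, c("TRIAVA", "BKGRND"))
  sc <- generate_trap_scene(scene_config(width = 320, height = 240, counts = c(),
                                         border_margin = 60, rng_seed = 1))
  write_category_overlay(map, sc$image, file.path(tmp, "overlay.png"))
  expect_true(file.exists(file.path(tmp, "overlay.png")))
})

test_that("detections round-trip through the marker-table dialect", {
  det <- structure(data.frame(x = c(120L, 400L), y = c(130L, 300L),
                              label = c("TRIAVA", "MACRPY"),
                              score = c(2.5, 1.0)),
                   class = c("detection_list", "data.frame"))
  tab <- detections_to_markers(det, image_id = "scene-1")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_markers(tab, tmp)
  back <- read_markers(tmp)
  expect_equal(back$x, det$x)
  expect_equal(back$y, det$y)
  expect_equal(back$label, det$label)
  expect_true(all(back$dataset_tag == "detected"))
})
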