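test_that("patch rendering is deterministic and dimensionally correct", {
  spec <- default_class_specs()$BEMITA
  p1 <- render_insect_patch(spec, 0, 7)
  p2 <- render_insect_patch(spec, 0, 7)
  expect_identical(p1$patch, p2$patch)
  expect_identical(p1$mask, p2$mask)
  expect_equal(dim(p1$patch), c(201, 201, 3))
  expect_true(all(p1$patch >= 0 & p1$patch <= 255))
  p3 <- render_insect_patch(spec, 0, 8)
  expect_false(identical(p1$patch, p3$patch))
})

test_that("the background class renders no insect", {
  r <- render_insect_patch(default_class_specs()$BKGRND, 0, 3)
  expect_false(any(r$mask))
  same_bg <- render_insect_patch(default_class_specs()$BKGRND, 1, 3)
  expect_identical(r$patch, same_bg$patch)  # decay has nothing to fade
})

test_that("foreground contrast decreases monotonically with decay", {
  specs <- default_class_specs()
  for (lab in c("BEMITA", "MACRPY")) {
    mask <- render_insect_patch(specs[[lab]], 0, 7)$mask
    bg <- render_insect_patch(specs$BKGRND, 0, 7)$patch
    dist_at <- function(decay) {
      p <- render_insect_patch(specs[[lab]], decay, 7)$patch
      d <- sqrt((p[, , 1] - bg[, , 1])^2 + (p[, , 2] - bg[, , 2])^2 +
                  (p[, , 3] - bg[, , 3])^2)
      mean(d[mask])
    }
    d <- vapply(c(0, 0.5, 1), dist_at, numeric(1))
    expect_true(all(diff(d) < 0))
  }
  expect_error(render_insect_patch(default_class_specs()$BEMITA, 1.5, 1),
               "decay")
})

test_that("the whitefly pair shares geometry and differs only in wing colour", {
  specs <- default_class_specs()
  expect_identical(specs$BEMITA$shape_params, specs$TRIAVA$shape_params)
  expect_identical(specs$BEMITA$texture_params, specs$TRIAVA$texture_params)
  expect_identical(specs$BEMITA$colour_params$body, specs$TRIAVA$colour_params$body)
  expect_false(identical(specs$BEMITA$colour_params$wing,
                         specs$TRIAVA$colour_params$wing))

  b <- render_insect_patch(specs$BEMITA, 0, 11)
  t <- render_insect_patch(specs$TRIAVA, 0, 11)
  expect_identical(b$mask, t$mask)
  # wing regions (mask pixels differing between the two renders) differ in
  # mean colour
  diffpix <- b$mask & (b$patch[, , 1] != t$patch[, , 1] |
                         b$patch[, , 2] != t$patch[, , 2])
  expect_gt(sum(diffpix), 50)
  expect_gt(mean(b$patch[, , 3][diffpix]) - mean(t$patch[, , 3][diffpix]), 20)
})

test_that("unknown labels are rejected at spec construction", {
  expect_error(class_spec("APHID",
                          list(body_axes = c(5, 5), wing_count = 0L, antenna = FALSE),
                          list(body = c(0, 0, 0), wing = c(0, 0, 0), wing_opacity = 0),
                          list(speckle_density = 1, blob_scale = 1)),
               "unknown")
})

test_that("scene generation conserves counts and separations", {
  empty <- generate_trap_scene(scene_config(width = 640, height = 480,
                                            counts = c(), border_margin = 110,
                                            rng_seed = 5))
  expect_equal(nrow(empty$markers), 0)
  expect_equal(dim(empty$image), c(480, 640, 3))

  cfg <- scene_config(width = 900, height = 700, counts = c(TRIAVA = 10),
                      min_separation = 60, border_margin = 110, rng_seed = 6)
  sc <- generate_trap_scene(cfg)
  expect_equal(nrow(sc$markers), 10)
  expect_true(all(sc$markers$label == "TRIAVA"))

  cfg2 <- scene_config(width = 900, height = 700,
                       counts = c(BEMITA = 5, MACRPY = 5),
                       min_separation = 60, border_margin = 110, rng_seed = 7)
  sc2 <- generate_trap_scene(cfg2)
  d <- as.matrix(stats::dist(cbind(sc2$markers$x, sc2$markers$y)))
  expect_true(all(d[upper.tri(d)] >= 60 - 1.5))  # centres round to integers

  # identical config => bit-identical scene and markers
  again <- generate_trap_scene(cfg2)
  expect_identical(again$image, sc2$image)
  expect_identical(again$markers, sc2$markers)
})

test_that("clutter objects are drawn but never annotated", {
  cfg <- scene_config(width = 800, height = 600,
                      counts = c(TRIAVA = 2, CLUTTER = 3),
                      min_separation = 60, border_margin = 110, rng_seed = 9)
  sc <- generate_trap_scene(cfg)
  expect_equal(sum(sc$markers$label == "TRIAVA"), 2)
  expect_false("CLUTTER" %in% sc$markers$label)
  expect_equal(nrow(sc$clutter), 3)
  # the clutter really is drawn: scene differs from the clutter-free one
  sc0 <- generate_trap_scene(scene_config(width = 800, height = 600,
                                          counts = c(TRIAVA = 2),
                                          min_separation = 60,
                                          border_margin = 110, rng_seed = 9))
  expect_false(identical(sc$image, sc0$image))
})

test_that("infeasible placements fail with the class named", {
  cfg <- scene_config(width = 460, height = 460, counts = c(MACRPY = 4),
                      min_separation = 400, border_margin = 110, rng_seed = 1)
  expect_error(generate_trap_scene(cfg), "MACRPY")
})

test_that("generated datasets keep exact per-class bookkeeping", {
  counts <- stats::setNames(rep(20L, 5), trap_taxonomy())
  set <- generate_dataset(counts, rng_seed = 31, dataset_tag = "Lab0d",
                          size = 61)
  expect_equal(length(set$patches), 100)
  expect_equal(as.integer(table(set$info$label)[trap_taxonomy()]),
               rep(20L, 5))
  expect_true(all(set$info$dataset_tag == "Lab0d"))
  expect_true(all(vapply(set$patches, function(p) all(dim(p) == c(61, 61, 3)),
                         logical(1))))
  again <- generate_dataset(counts, rng_seed = 31, dataset_tag = "Lab0d",
                            size = 61)
  expect_identical(set$patches, again$patches)
  expect_identical(set$info, again$info)
})

test_that("decay levels are sampled at their configured frequencies", {
  set <- generate_dataset(c(TRIAVA = 1000L), decay_levels = c(0, 1),
                          decay_probs = c(0.8, 0.2), rng_seed = 41, size = 31)
  n0 <- sum(set$info$decay == 0)
  # two-sided 99% binomial interval oracle for p = 0.8, n = 1000
  expect_gte(n0, stats::qbinom(0.005, 1000, 0.8))
  expect_lte(n0, stats::qbinom(0.995, 1000, 0.8))
  expect_true(all(set$info$decay %in% c(0, 1)))
})

test_that("scene configurations load from YAML", {
  tmp <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("width: 640", "height: 480", "decay: 0.25",
               "min_separation: 60", "border_margin: 110", "rng_seed: 12",
               "counts:", "  TRIAVA: 3", "  CLUTTER: 1"), tmp)
  cfg <- read_scene_config(tmp)
  expect_s3_class(cfg, "scene_config")
  expect_equal(cfg$width, 640L)
  expect_equal(cfg$decay, 0.25)
  expect_equal(cfg$counts[["TRIAVA"]], 3)
  sc <- generate_trap_scene(cfg)
  expect_equal(nrow(sc$markers), 3)
})
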