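make_table <- function(n = 3) {
  data.frame(image_id = rep("img1", n),
             x = as.integer(seq(120, by = 37, length.out = n)),
             y = as.integer(seq(150, by = 21, length.out = n)),
             label = rep(c("BEMITA", "MACRPY", "BKGRND"), length.out = n),
             dataset_tag = rep("Lab0d", n))
}

test_that("marker tables round-trip through their tab-delimited files", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tab <- make_table(3)
  write_markers(tab, tmp)
  back <- read_markers(tmp)
  expect_equal(as.data.frame(back), tab, ignore_attr = TRUE)

  empty <- tab[0, ]
  write_markers(empty, tmp)
  expect_equal(readLines(tmp), "image_id\tx\ty\tlabel\tdataset_tag")
  expect_equal(nrow(read_markers(tmp)), 0)
})

test_that("marker parsing rejects bad input with located errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  tab <- make_table(2); tab$label[2] <- "APHID"
  write_markers(tab, tmp)
  expect_error(read_markers(tmp), "APHID")

  writeLines(c("image_id\tx\ty\tlabel\tdataset_tag",
               "img1\t10\t20\tBEMITA\tLab0d",
               "img1\t10\tBEMITA\tLab0d"), tmp)
  expect_error(read_markers(tmp), "line 3")

  writeLines(c("image_id\tx\ty\tlabel\tdataset_tag",
               "img1\tten\t20\tBEMITA\tLab0d"), tmp)
  expect_error(read_markers(tmp), "line 2")

  write_markers(make_table(1), tmp)   # marker at (120, 150)
  expect_error(read_markers(tmp, image_size = c(100, 100)), "bounds")
  expect_error(read_markers(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("cropping centres each patch exactly on its marker", {
  img <- with_seed_local(5, array(sample(0:255, 400 * 500 * 3, TRUE),
                                  dim = c(400, 500, 3)))
  markers <- as.data.frame(make_table(3))
  set <- crop_subimages(img, markers, size = 201)
  expect_equal(length(set$patches), 3)
  for (i in 1:3) {
    p <- set$patches[[i]]
    expect_equal(dim(p), c(201, 201, 3))
    # direct-indexing oracle: patch(i, j) = image(y - 100 + i, x - 100 + j)
    xi <- markers$x[i]; yi <- markers$y[i]
    expect_identical(p[, , 1],
                     img[(yi - 100 + 1):(yi + 100 + 1),
                         (xi - 100 + 1):(xi + 100 + 1), 1])
    expect_equal(p[101, 101, ], img[yi + 1, xi + 1, ])  # centre pixel
  }
})

test_that("a marker at the exact centre of a patch-sized image crops the whole image", {
  img <- with_seed_local(6, array(sample(0:255, 201 * 201 * 3, TRUE),
                                  dim = c(201, 201, 3)))
  markers <- data.frame(image_id = "img", x = 100L, y = 100L,
                        label = "TRIAVA", dataset_tag = "Lab0d")
  set <- crop_subimages(img, markers, size = 201)
  expect_identical(set$patches[[1]], img)
})

test_that("border markers follow the edge policy", {
  img <- with_seed_local(7, array(sample(0:255, 300 * 300 * 3, TRUE),
                                  dim = c(300, 300, 3)))
  markers <- data.frame(image_id = "img", x = c(5L, 150L), y = c(5L, 150L),
                        label = "BEMITA", dataset_tag = "Lab0d")
  expect_message(skipped <- crop_subimages(img, markers, edge_policy = "skip"),
                 "skipped 1")
  expect_equal(length(skipped$patches), 1)
  expect_equal(attr(skipped, "skipped"), 1L)

  refl <- crop_subimages(img, markers, edge_policy = "reflect")
  expect_equal(length(refl$patches), 2)
  p <- refl$patches[[1]]
  expect_equal(dim(p), c(201, 201, 3))
  expect_equal(p[101, 101, ], img[6, 6, ])           # centre = marker pixel
  # mirrored without repeating the border pixel: offset -12 from source row 6
  # lands at virtual row -6, which reflects to row 2 - (-6) = 8
  expect_equal(p[101 - 12, 101, ], img[8, 6, ])

  expect_error(crop_subimages(img, markers, size = 200), "odd")
  bad <- data.frame(image_id = "img", x = 400L, y = 10L, label = "BEMITA",
                    dataset_tag = "Lab0d")
  expect_error(crop_subimages(img, bad), "outside")
})

test_that("the 75/25 split is stratified, exhaustive and reproducible", {
  labels <- rep(c("A", "B", "C", "D"), each = 100)
  sp <- split_train_opt(labels, 0.75, rng_seed = 3)
  expect_equal(length(intersect(sp$model, sp$optimization)), 0)
  expect_equal(sort(c(sp$model, sp$optimization)), seq_along(labels))
  for (cl in c("A", "B", "C", "D")) {
    expect_equal(sum(labels[sp$model] == cl), 75)
    expect_equal(sum(labels[sp$optimization] == cl), 25)
  }
  expect_identical(split_train_opt(labels, 0.75, rng_seed = 3), sp)
  expect_false(identical(split_train_opt(labels, 0.75, rng_seed = 4)$model,
                         sp$model))
})

test_that("small classes keep at least one held-out record or stay whole", {
  sp4 <- split_train_opt(rep("A", 4), 0.75, rng_seed = 1)  # floor(3) / 1
  expect_equal(length(sp4$model), 3)
  expect_equal(length(sp4$optimization), 1)
  # fraction high enough to swallow the class: still hold one out
  sp_hi <- split_train_opt(rep("A", 3), 0.99, rng_seed = 1)
  expect_equal(length(sp_hi$model), 2)
  expect_warning(sp1 <- split_train_opt(c("A", "B", "B", "B", "B"), 0.75,
                                        rng_seed = 1),
                 "kept whole")
  expect_true(1 %in% sp1$model)
  expect_error(split_train_opt(rep("A", 10), 1.2), "fraction")
})

test_that("pooling relabels without changing record counts", {
  labs <- c(rep("BEMITA", 10), rep("TRIAVA", 20), rep("MACRPY", 5))
  sch <- pooling_scheme(categorical = TRUE)
  pooled <- apply_pooling(labs, sch)
  expect_equal(length(pooled), 35)
  expect_equal(sum(pooled == "BEM-TRI"), 30)
  expect_equal(sum(pooled == "MACRPY"), 5)
  expect_equal(pooled_taxonomy(sch), trap_taxonomy(pooled = TRUE))

  ident <- pooling_scheme(categorical = FALSE)
  expect_identical(apply_pooling(labs, ident), labs)

  expect_error(apply_pooling(c("BEMITA", "WASP"), sch), "domain")
})

test_that("temporal pooling merges the fresh and aged sets tag-for-tag", {
  # dataset sizes as in the laboratory sets: 5866 fresh + 1435 aged
  tab <- data.frame(image_id = "x", x = 0L, y = 0L,
                    label = sample(trap_taxonomy(), 7301, TRUE),
                    dataset_tag = rep(c("Lab0d", "Lab7d"), c(5866, 1435)))
  sch <- pooling_scheme(categorical = FALSE, temporal = TRUE)
  pooled <- apply_pooling(tab, sch)
  expect_equal(nrow(pooled), 7301)
  expect_true(all(pooled$dataset_tag == "Lab0d-7d"))
})

test_that("scenes round-trip through PNG", {
  sc <- generate_trap_scene(scene_config(width = 320, height = 240,
                                         counts = c(ENCAFO = 1),
                                         min_separation = 10,
                                         border_margin = 60, rng_seed = 2))
  tmp <- withr::local_tempfile(fileext = ".png")
  write_scene(sc$image, tmp)
  back <- read_scene(tmp)
  expect_identical(back, sc$image)
})
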