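test_that("vocsize 1 yields the coordinate-wise mean of the pool", {
  x <- random_descriptors(40, seed = 1)
  d <- build_dictionary(x, 1, seed = 2)
  expect_equal(as.numeric(d$centres), unname(colMeans(x)), tolerance = 1e-10)
})

test_that("a pool of exactly vocsize distinct points is reproduced with zero inertia", {
  x <- random_descriptors(8, seed = 3)
  d <- build_dictionary(x, 8, seed = 4)
  expect_equal(d$inertia, 0, tolerance = 1e-6)
  reord <- trapbovw:::vq_assign_cpp(x, d$centres)
  expect_equal(sort(reord), 1:8)
  expect_equal(x[order(reord), ], d$centres[sort(reord), ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("k-means recovers the means of a separated Gaussian mixture", {
  mu <- with_seed_local(11, matrix(stats::runif(3 * 128, 0, 255), 3, 128))
  sigma <- 2
  n_per <- 120
  x <- with_seed_local(12, do.call(rbind, lapply(1:3, function(k)
    matrix(stats::rnorm(n_per * 128, mean = rep(mu[k, ], each = n_per),
                        sd = sigma), n_per, 128))))
  truth <- rep(1:3, each = n_per)
  sample_means <- do.call(rbind, lapply(1:3, function(k)
    colMeans(x[truth == k, ])))
  d <- build_dictionary(x, 3, seed = 13)
  # match each centre to its nearest true sample mean, require all distinct
  pick <- trapbovw:::vq_assign_cpp(d$centres, sample_means)
  expect_equal(sort(pick), 1:3)
  tol <- 3 * sigma / sqrt(n_per)  # per-coordinate 3-sigma band on the mean
  for (k in 1:3)
    expect_lt(max(abs(d$centres[k, ] - sample_means[pick[k], ])), tol * 4)
})

test_that("k-means inertia is non-increasing over the iteration budget", {
  x <- random_descriptors(300, seed = 21)
  inertias <- vapply(c(1L, 2L, 4L, 8L, 20L), function(it)
    build_dictionary(x, 10, seed = 22, max_iter = it, n_init = 1)$inertia,
    numeric(1))
  expect_true(all(diff(inertias) <= 1e-6))
})

test_that("dictionary build is deterministic and refuses undersized pools", {
  x <- random_descriptors(60, seed = 31)
  d1 <- build_dictionary(x, 5, seed = 32)
  d2 <- build_dictionary(x, 5, seed = 32)
  expect_identical(d1$centres, d2$centres)
  expect_error(build_dictionary(x[1:4, ], 5), "smaller than vocsize")
})

test_that("exact VQ assigns the Euclidean-nearest centre, ties to lowest index", {
  d <- build_dictionary(random_descriptors(30, seed = 41), 10, seed = 42)
  # a descriptor equal to a centre maps to that centre
  expect_equal(quantize_vq(d$centres[7, , drop = FALSE], d), 7L)
  # integer-coordinate tie: query midway between centres 2 and 5
  centres <- matrix(0, 6, 128)
  centres[2, 1] <- 2; centres[5, 1] <- -2; centres[c(1, 3, 4, 6), 2] <- 90
  dict <- structure(list(centres = centres, vocsize = 6L, seed = 0L,
                         n_descriptors = 6L, inertia = 0,
                         colour_space = NA_character_),
                    class = "visual_dictionary")
  expect_equal(quantize_vq(matrix(0, 1, 128), dict), 2L)
})

test_that("exact VQ agrees with an independent distance-matrix oracle", {
  for (seed in 1:25) {
    x <- random_descriptors(40, seed = 100 + seed)
    centres <- random_descriptors(12, seed = 200 + seed)
    dict <- structure(list(centres = centres, vocsize = 12L, seed = 0L,
                           n_descriptors = 12L, inertia = 0,
                           colour_space = NA_character_),
                      class = "visual_dictionary")
    expect_equal(quantize_vq(x, dict), vq_oracle(x, centres))
  }
})

test_that("exhaustive k-d tree search equals exact VQ", {
  for (seed in 1:25) {
    x <- random_descriptors(30, seed = 300 + seed)
    centres <- random_descriptors(40, seed = 400 + seed)
    dict <- structure(list(centres = centres, vocsize = 40L, seed = 0L,
                           n_descriptors = 40L, inertia = 0,
                           colour_space = NA_character_),
                      class = "visual_dictionary")
    kd <- quantize_kdtree(x, dict)
    expect_equal(as.integer(kd), quantize_vq(x, dict))
  }
  # single-word dictionary: everything maps to the only word
  dict1 <- structure(list(centres = random_descriptors(1, seed = 5),
                          vocsize = 1L, seed = 0L, n_descriptors = 1L,
                          inertia = 0, colour_space = NA_character_),
                     class = "visual_dictionary")
  expect_equal(as.integer(quantize_kdtree(random_descriptors(7, seed = 6), dict1)),
               rep(1L, 7))
})

test_that("bounded backtracking reports its mismatch rate instead of hiding it", {
  # adversarial pair: the true nearest centre sits across the split plane
  centres <- matrix(0, 2, 128)
  centres[2, 1] <- 2
  dict <- structure(list(centres = centres, vocsize = 2L, seed = 0L,
                         n_descriptors = 2L, inertia = 0,
                         colour_space = NA_character_),
                    class = "visual_dictionary")
  q <- matrix(0, 1, 128); q[1, 1] <- 1.2   # nearest is centre 2
  approx <- quantize_kdtree(q, dict, max_comparisons = 1, leaf_size = 1)
  expect_equal(attr(approx, "mismatch_rate"), 1)
  expect_equal(as.integer(approx), 1L)
  exact <- quantize_kdtree(q, dict, leaf_size = 1)
  expect_equal(as.integer(exact), 2L)
})

test_that("BoVW encoding counts, normalizes and conserves mass", {
  v <- encode_bovw(c(1L, 1L, 4L), 4, "none")
  expect_equal(v$counts, c(2, 0, 0, 1))
  expect_equal(v$n_keypoints, 3L)
  l1 <- encode_bovw(c(1L, 1L, 4L), 4, "l1")
  expect_equal(l1$counts, c(2 / 3, 0, 0, 1 / 3))
  empty <- encode_bovw(integer(0), 4, "l1")
  expect_equal(empty$counts, rep(0, 4))
  expect_equal(empty$n_keypoints, 0L)
  expect_error(encode_bovw(c(1L, 5L), 4), "1..vocsize")

  for (seed in 1:20) {
    a <- with_seed_local(seed, sample.int(50, 200, replace = TRUE))
    v <- encode_bovw(a, 50, "none")
    expect_equal(sum(v$counts), length(a))
    expect_equal(sum(encode_bovw(a, 50, "l1")$counts), 1, tolerance = 1e-12)
  }
})

test_that("permuting dictionary rows permutes BoVW coordinates identically", {
  x <- random_descriptors(60, seed = 51)
  centres <- random_descriptors(15, seed = 52)
  perm <- with_seed_local(53, sample.int(15))
  mk <- function(cs) structure(list(centres = cs, vocsize = 15L, seed = 0L,
                                    n_descriptors = 15L, inertia = 0,
                                    colour_space = NA_character_),
                               class = "visual_dictionary")
  v1 <- encode_bovw(quantize_vq(x, mk(centres)), 15, "none")$counts
  v2 <- encode_bovw(quantize_vq(x, mk(centres[perm, ])), 15, "none")$counts
  expect_equal(v2, v1[perm])
})

test_that("dictionaries round-trip through their text container", {
  d <- build_dictionary(random_descriptors(50, seed = 61), 6, seed = 62,
                        colour_space = "greyscale")
  tmp <- file.path(withr::local_tempdir(), "dict")
  write_dictionary(d, tmp)
  back <- read_dictionary(tmp)
  expect_equal(back$centres, d$centres, tolerance = 1e-12)
  expect_equal(back$vocsize, d$vocsize)
  expect_equal(back$inertia, d$inertia, tolerance = 1e-8)
  expect_equal(back$colour_space, "greyscale")
})
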