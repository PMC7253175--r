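test_that("perfectly separable modes threshold at the gap floors", {
  x <- rep(c(10, 100, 170, 240), each = 50)
  res <- multi_otsu(gray_histogram(x), 4)
  # any tuple inside the gaps is optimal; the smallest-tuple tie-break
  # forces the bin immediately after each occupied mode
  expect_identical(res$thresholds, c(11, 101, 171))
})

test_that("between-class variance can be recomputed from the histogram and thresholds", {
  set.seed(10)
  x <- round(c(rnorm(400, 60, 10), rnorm(400, 150, 12), rnorm(200, 220, 8)))
  x <- pmin(pmax(x, 0), 255)
  h <- gray_histogram(x)
  res <- multi_otsu(h, 3)
  cls <- findInterval(h$values, res$thresholds)
  w <- h$counts / sum(h$counts)
  mu <- sum(w * h$values)
  bcv <- sum(vapply(unique(cls), function(c) {
    wk <- sum(w[cls == c])
    (sum(w[cls == c] * h$values[cls == c]) / wk - mu)^2 * wk
  }, 0))
  expect_equal(res$between_class_variance, bcv, tolerance = 1e-10)
})

test_that("dynamic programming equals exhaustive search on random histograms", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(8:64, 1)
    h <- structure(list(breaks = 0:n, counts = rpois(n, 20) + (runif(n) < 0.8),
                        values = 0:(n - 1)), class = "gray_histogram")
    if (sum(h$counts > 0) < 4) next
    got <- multi_otsu(h, 4)
    ref <- brute_otsu(h, 4)
    expect_identical(got$thresholds, ref$thresholds, label = paste("hist", i))
    expect_equal(got$between_class_variance, ref$between_class_variance,
                 tolerance = 1e-12)
  }
})

test_that("thresholds are shift-equivariant and invariant to count rescaling", {
  set.seed(12)
  x <- round(c(rnorm(300, 50, 8), rnorm(300, 120, 9), rnorm(300, 200, 7)))
  x <- pmin(pmax(x, 0), 235)
  base <- multi_otsu(gray_histogram(x), 4)
  shifted <- multi_otsu(gray_histogram(x + 20), 4)
  expect_identical(shifted$thresholds, base$thresholds + 20)
  expect_equal(shifted$between_class_variance, base$between_class_variance,
               tolerance = 1e-9)

  h <- gray_histogram(x)
  h5 <- structure(list(breaks = h$breaks, counts = h$counts * 5, values = h$values),
                  class = "gray_histogram")
  expect_identical(multi_otsu(h5, 4)$thresholds, base$thresholds)
  expect_equal(multi_otsu(h5, 4)$between_class_variance,
               base$between_class_variance, tolerance = 1e-12)
})

test_that("empty bins outside the data do not move thresholds", {
  h <- structure(list(breaks = 0:8, counts = c(5, 0, 7, 0, 6, 0, 4, 0),
                      values = 0:7), class = "gray_histogram")
  base <- multi_otsu(h, 4)
  padded <- structure(list(breaks = 0:12,
                           counts = c(h$counts, 0, 0, 0, 0), values = 0:11),
                      class = "gray_histogram")
  expect_identical(multi_otsu(padded, 4)$thresholds, base$thresholds)
})

test_that("histograms with too few occupied bins are rejected", {
  expect_error(multi_otsu(gray_histogram(rep(c(10, 200), 50)), 4), "non-empty")
  h0 <- structure(list(breaks = 0:4, counts = rep(0L, 4), values = 0:3),
                  class = "gray_histogram")
  expect_error(multi_otsu(h0, 2), "empty")
})

test_that("voxel classification uses lower-inclusive tier boundaries", {
  tiers <- density_tiers()  # 0.632 / 1.143 / 1.528
  v <- volume3d(array(c(1.2, 0.5, 1.143, 1.528, 0.632, 0.6319),
                      dim = c(6, 1, 1)), 9, "density")
  lab <- classify_voxels(v, tiers)
  expect_identical(as.integer(lab), c(2L, 0L, 2L, 3L, 1L, 0L))
  # partition: every voxel in exactly one tier
  expect_equal(sum(table(unclass(lab))), 6)
  expect_error(classify_voxels(
    volume3d(array(1, dim = c(2, 2, 1)), 9, "grayscale", bit_depth = 8), tiers),
    "density")
})

test_that("cohort thresholds: identical samples give zero spread, shifts average", {
  set.seed(13)
  base_arr <- array(round(pmin(pmax(
    c(rnorm(4000, 40, 6), rnorm(3000, 120, 8), rnorm(3000, 200, 7)), 0), 235)),
    dim = c(10, 10, 100))
  mk <- function(shift) volume3d(base_arr + shift, 9, "grayscale", bit_depth = 8)
  cur <- fit_calibration(c(0, 200), c(0, 2))

  same <- derive_reference_thresholds(list(mk(0), mk(0), mk(0)), calibration = cur)
  expect_equal(unname(same$provenance$spread), c(0, 0, 0))
  one <- multi_otsu(gray_histogram(mk(0)), 4)
  expect_equal(unname(same$provenance$consensus_gray), one$thresholds)

  shifted <- derive_reference_thresholds(list(mk(0), mk(2), mk(4)), calibration = cur)
  expect_equal(unname(shifted$provenance$consensus_gray), one$thresholds + 2)
  expect_error(derive_reference_thresholds(list(mk(0)), calibration = cur),
               "at least 2")
})

test_that("percent spread reproduces range-over-midpoint arithmetic", {
  expect_equal(percent_spread(c(3, 5)), 50)
  expect_equal(percent_spread(c(7, 7, 7)), 0)
  expect_gte(percent_spread(runif(5, 1, 2)), 0)
})
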