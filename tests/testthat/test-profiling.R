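test_that("slice percentages follow constructed voxel counts", {
  # one slice: envelope 40x25 = 1000 voxels; 200 low, 100 mid, 50 high
  lab <- array(0L, dim = c(40, 25, 1))
  lab[1:8, , 1] <- 1L    # 200
  lab[9:12, , 1] <- 2L   # 100
  lab[13:14, , 1] <- 3L  # 50
  labels <- as_tier_labels(lab)
  env <- array(TRUE, dim = dim(lab))
  prof <- slice_profile(labels, envelope = env)
  pct <- setNames(prof$percent, prof$tier)
  expect_equal(unname(pct[c("low", "mid", "high")]), c(20, 10, 5))
  expect_equal(prof$cross_section_um2[1], 1000 * 81)
  # conservation: tier areas partition the envelope exactly
  expect_equal(sum(prof$area_um2), 1000 * 81)
})

test_that("an all-high slice profiles at 100 percent", {
  lab <- array(3L, dim = c(6, 6, 2))
  prof <- slice_profile(as_tier_labels(lab))
  expect_true(all(prof$percent[prof$tier == "high"] == 100))
  expect_true(all(prof$percent[prof$tier %in% c("low", "mid")] == 0))
})

test_that("ROI summary equals the cross-section-weighted mean of slice profiles", {
  spec <- phantom_spec(nx = 48, ny = 48, nz = 40,
                       cortex_outer_radii = c(190, 160), cortex_thickness = 63,
                       strut_count = 6, psf_sigma = 0, noise_sd = 0, seed = 9)
  ph <- generate_phantom(spec)
  labels <- ph$truth$label_volume
  env <- envelope_mask(unclass(labels) > 0)
  roi <- select_roi(40 * 9, 9, 1, offset_fraction = 0.1, length_fraction = 0.5,
                    n_slices_total = 40)
  summ <- roi_summary(labels, roi, envelope = env)
  prof <- slice_profile(labels, roi, envelope = env)
  for (t in c("low", "mid", "high")) {
    sel <- prof[prof$tier == t, ]
    weighted <- sum(sel$percent / 100 * sel$cross_section_um2) /
      sum(sel$cross_section_um2)
    expect_equal(unname(summ$fractions[t]), weighted, tolerance = 1e-12)
  }
  expect_equal(unname(sum(summ$fractions[c("low", "mid", "high")])),
               unname(summ$fractions["bone"]), tolerance = 1e-12)
})

test_that("zero-area slices are flagged as missing, not zero", {
  lab <- array(0L, dim = c(8, 8, 3))
  lab[3:5, 3:5, c(1, 3)] <- 2L
  prof <- slice_profile(as_tier_labels(lab))
  mid_empty <- prof$percent[prof$slice == 2]
  expect_true(all(is.na(mid_empty)))
  expect_equal(attr(prof, "empty_slices"), 2L)
  expect_error(roi_summary(as_tier_labels(array(0L, dim = c(4, 4, 2))),
                           select_roi(18, 9, 1, 0, 1)),
               "zero cross-sectional area")
})

test_that("pseudocolour mapping is exact and reversible", {
  set.seed(5)
  lab <- matrix(sample(0:3, 144, replace = TRUE), 12, 12)
  img <- pseudocolour_slice(lab)
  expect_identical(unpseudocolour_slice(img), lab)
  # counts preserved per colour
  expect_equal(sum(img[, , 1] == 0 & img[, , 2] == 0 & img[, , 3] == 0), 0)
  expect_error(pseudocolour_slice(lab, palette = c(low = "#000000")), "missing")
})

test_that("pseudocolour export writes one PNG per slice plus the palette", {
  td <- withr::local_tempdir()
  lab <- as_tier_labels(array(sample(0:3, 4 * 4 * 3, TRUE), dim = c(4, 4, 3)))
  files <- pseudocolour_export(lab, td)
  expect_true(all(file.exists(files)))
  expect_length(grep("slice_\\d+\\.png$", files), 3)
  back <- png::readPNG(grep("slice_000", files, value = TRUE))
  expect_identical(unpseudocolour_slice(back), unclass(lab)[, , 1])
})
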