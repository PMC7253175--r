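test_that("noiseless single-tier cylinder yields exact truth and two gray values", {
  ph <- generate_phantom(phantom_preset("cylinder"))
  expect_identical(sort(unique(as.vector(ph$volume$voxels))), c(0, 135))
  fr <- ph$truth$roi_fractions
  expect_equal(unname(fr["mid"]), 1)
  expect_equal(unname(fr["low"]), 0)
  expect_equal(unname(fr["high"]), 0)
  expect_equal(unname(fr["bone"]), 1)
  # per-slice: mid fraction is cylinder voxels over envelope voxels = 1
  mid <- ph$truth$per_slice[ph$truth$per_slice$tier == "mid", ]
  expect_true(all(mid$percent == 100))
})

test_that("an embedded 3x3x3 cavity is one closed pore of 19,683 um^3", {
  spec <- phantom_spec(nx = 40, ny = 40, nz = 30,
                       cortex_outer_radii = c(108, 108), cortex_thickness = 120,
                       gradient = function(z) c(low = 0, mid = 1, high = 0),
                       pores = list(pore_box(c(19, 19, 14), c(3, 3, 3))),
                       pore_lining = 0, surface_lining = 0,
                       psf_sigma = 0, noise_sd = 0)
  ph <- generate_phantom(spec)
  inv <- ph$truth$pore_inventory
  expect_equal(nrow(inv), 1)
  expect_equal(inv$voxels, 27)
  expect_equal(inv$volume_um3, 27 * 9^3)  # 19,683
  expect_equal(inv$status, "closed")
})

test_that("a linear gradient gives a non-decreasing high-tier slice profile", {
  spec <- phantom_spec(nx = 48, ny = 48, nz = 60,
                       cortex_outer_radii = c(180, 180), cortex_thickness = 200,
                       surface_lining = 0, psf_sigma = 0, noise_sd = 0)
  ph <- generate_phantom(spec)
  high <- ph$truth$per_slice[ph$truth$per_slice$tier == "high", ]
  expect_true(all(diff(high$percent) >= 0))
  expect_gt(high$percent[nrow(high)], high$percent[1])
})

test_that("generation is deterministic for a fixed seed and truth ignores noise", {
  a <- generate_phantom(phantom_preset("gradient", seed = 5))
  b <- generate_phantom(phantom_preset("gradient", seed = 5))
  expect_identical(a$volume$voxels, b$volume$voxels)
  c <- generate_phantom(phantom_preset("gradient", seed = 6))
  expect_identical(unclass(a$truth$label_volume), unclass(c$truth$label_volume))
  expect_equal(a$truth$roi_fractions, c$truth$roi_fractions)
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("geometry violations are reported by element", {
  expect_error(phantom_spec(nx = 20, ny = 20, nz = 20,
                            cortex_outer_radii = c(300, 300)),
               "cortex outer radii")
  expect_error(phantom_spec(pores = list(pore_sphere(c(5, 5, 5), 900))),
               "pore 1")
  expect_error(phantom_spec(pores = list(pore_sphere(c(48, 48, 60), 4))),
               "radius below one voxel")
  expect_error(phantom_spec(nx = 2, ny = 2, nz = 0), "too small")
})

test_that("reference cohorts share truth; shifts have the requested spread", {
  spec <- phantom_preset("cylinder")
  co0 <- generate_reference_cohort(spec, 3, gray_shift_sd = 0)
  expect_identical(co0[[1]]$volume$voxels, co0[[2]]$volume$voxels)

  spec2 <- phantom_spec(nx = 32, ny = 32, nz = 10,
                        cortex_outer_radii = c(100, 100), cortex_thickness = 120,
                        surface_lining = 0, psf_sigma = 0, noise_sd = 1, seed = 2)
  co <- generate_reference_cohort(spec2, 10, gray_shift_sd = 5, seed = 21)
  shifts <- vapply(co, function(m) m$truth$gray_shift, 0)
  # sample sd of 10 N(0,5) draws: within 3 standard errors of 5
  se <- 5 / sqrt(2 * (10 - 1))
  expect_lt(abs(sd(shifts) - 5), 3 * se)
  # labels are captured pre-shift: every member carries the base truth
  base <- generate_phantom(spec2)
  for (m in co) expect_equal(m$truth$roi_fractions, base$truth$roi_fractions)
  expect_error(generate_reference_cohort(spec2, 1), "n >= 2")
})

test_that("pore inventory volumes sum exactly to porosity times compartment", {
  spec <- phantom_spec(nx = 60, ny = 60, nz = 40,
                       cortex_outer_radii = c(240, 220), cortex_thickness = 300,
                       pores = list(pore_sphere(c(30, 30, 20), 45),
                                    pore_box(c(12, 40, 8), c(4, 4, 6))),
                       psf_sigma = 0, noise_sd = 0)
  ph <- generate_phantom(spec)
  inv <- ph$truth$pore_inventory
  vz3 <- 9^3
  expect_equal(sum(inv$volume_um3),
               ph$truth$true_porosity * ph$truth$compartment_voxels * vz3)
})

test_that("noiseless phantoms classify back to their exact truth labels", {
  spec <- phantom_spec(nx = 48, ny = 48, nz = 30,
                       cortex_outer_radii = c(190, 170), cortex_thickness = 250,
                       pores = list(pore_sphere(c(24, 24, 15), 36)),
                       psf_sigma = 0, noise_sd = 0)
  ph <- generate_phantom(spec)
  # thresholds halfway between the tier gray means, on the 0.01 density line
  cur <- fit_calibration(c(0, 100), c(0, 1))
  mids <- (spec$tier_gray[-4] + spec$tier_gray[-1]) / 2
  tiers <- density_tiers(gray_to_density(mids[1], cur),
                         gray_to_density(mids[2], cur),
                         gray_to_density(mids[3], cur))
  lab <- classify_voxels(gray_to_density(ph$volume, cur), tiers)
  expect_identical(unclass(lab), unclass(ph$truth$label_volume))
})

test_that("calibration inserts sit outside the bone and recover the density line", {
  spec <- phantom_preset("gradient", seed = 3)
  ph <- generate_phantom(spec)
  ip <- measure_inserts(ph$volume, spec)
  cur <- fit_calibration(ip)
  expect_equal(cur$slope, 0.01, tolerance = 0.05)
  expect_lt(abs(cur$intercept), 0.05)
  # inserts never intersect the envelope used for ROI statistics
  env <- envelope_mask(unclass(ph$truth$label_volume) > 0)
  for (ins in spec$inserts) {
    disc <- outer(seq_len(spec$ny), seq_len(spec$nx), function(y, x)
      (x - ins$centre_xy[1])^2 + (y - ins$centre_xy[2])^2) <= (ins$radius / 9)^2
    for (z in ins$z_range[1]:ins$z_range[2])
      expect_equal(sum(env[, , z][disc]), 0)
  }
})
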