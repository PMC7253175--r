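test_that("bone mask threshold is lower-inclusive at 0.238", {
  v <- volume3d(array(c(0.5, 0.1, 0.238, 0.2379), dim = c(4, 1, 1)), 9, "density")
  m <- bone_mask(v)
  expect_identical(as.vector(m), c(TRUE, FALSE, TRUE, FALSE))
  expect_true(all(bone_mask(volume3d(array(0.5, dim = c(3, 3, 3)), 9, "density"))))
  expect_false(any(bone_mask(volume3d(array(0.1, dim = c(3, 3, 3)), 9, "density"))))
  gvol <- volume3d(array(1, dim = c(2, 2, 2)), 9, "grayscale", bit_depth = 8)
  expect_error(bone_mask(gvol), "density")
})

test_that("cube metrics match closed forms exactly (face-count surface)", {
  one <- pore_metrics(array(TRUE, dim = c(1, 1, 1)), 9)
  expect_equal(one$volume_um3, 729)
  expect_equal(one$surface_faces_um2, 486)
  expect_equal(one$sav_faces_um_inv, 6 / 9)

  cube <- pore_metrics(array(TRUE, dim = c(3, 3, 3)), 9)
  expect_equal(cube$volume_um3, 27 * 9^3)
  expect_equal(cube$surface_faces_um2, 54 * 9^2)
  expect_equal(cube$sav_faces_um_inv, 2 / 9)
  expect_error(pore_metrics(array(FALSE, dim = c(2, 2, 2)), 9), "empty")
})

test_that("a digitised sphere matches analytic volume, area and SA:V", {
  sph <- digitised_sphere(10)
  pm <- pore_metrics(sph, 1)
  expect_lt(abs(pm$volume_um3 - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.02)
  expect_lt(abs(pm$surface_mesh_um2 - 4 * pi * 100) / (4 * pi * 100), 0.05)
  expect_lt(abs(pm$sav_um_inv - 0.3) / 0.3, 0.05)
})

test_that("solid bone has no pores and zero porosity", {
  bone <- array(TRUE, dim = c(10, 10, 10))
  attr(bone, "voxel_size") <- 9
  tab <- label_pores(bone)
  expect_equal(nrow(tab), 0)
  rep <- porosity_report(tab)
  expect_equal(rep$porosity, 0)
  expect_error(label_pores(array(FALSE, dim = c(4, 4, 4)), voxel_size = 9),
               "empty bone mask")
})

test_that("a transcortical channel spanning the region is open; a cavity is closed", {
  bone <- array(FALSE, dim = c(15, 15, 10))
  d2 <- outer(1:15, 1:15, function(y, x) (x - 8)^2 + (y - 8)^2)
  for (z in 1:10) bone[, , z] <- d2 <= 36
  chan <- bone
  chan[8, 6, ] <- FALSE                  # z-spanning channel
  tab <- label_pores(chan, voxel_size = 9)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$status, "open")

  cav <- bone
  cav[7:9, 7:9, 5:7] <- FALSE            # fully embedded 3x3x3 cavity
  tab2 <- label_pores(cav, voxel_size = 9)
  expect_equal(nrow(tab2), 1)
  expect_equal(tab2$status, "closed")
  expect_equal(tab2$volume_um3, 19683)
  expect_false(tab2$at_limit)   # 19,683 um^3 is above the 5,000 um^3 floor

  tiny <- bone
  tiny[8, 8, 5] <- FALSE                 # single-voxel cavity, 729 um^3
  tab3 <- label_pores(tiny, voxel_size = 9)
  expect_true(tab3$at_limit)             # flagged, never dropped
})

test_that("open plus closed volume equals total pore volume exactly", {
  set.seed(6)
  for (i in 1:5) {
    bone <- array(TRUE, dim = c(20, 20, 16))
    holes <- sample(length(bone), 250)
    bone[holes] <- FALSE
    attr(bone, "voxel_size") <- 9
    tab <- label_pores(bone, mesh = FALSE)
    rep <- porosity_report(tab)
    expect_identical(rep$open_pore_volume_um3 + rep$closed_pore_volume_um3,
                     rep$total_pore_volume_um3)
    expect_identical(rep$total_pore_volume_um3, sum(tab$volume_um3))
    expect_lt(rep$porosity, 1)
  }
})

test_that("pore metrics are invariant under whole-voxel translation", {
  base <- array(FALSE, dim = c(24, 24, 24))
  base[6:10, 7:9, 8:12] <- TRUE
  shifted <- array(FALSE, dim = c(24, 24, 24))
  shifted[12:16, 13:15, 14:18] <- TRUE
  pm1 <- pore_metrics(base, 9)
  pm2 <- pore_metrics(shifted, 9)
  expect_equal(pm1$volume_um3, pm2$volume_um3)
  expect_equal(pm1$surface_mesh_um2, pm2$surface_mesh_um2, tolerance = 1e-9)
  expect_equal(pm1$surface_faces_um2, pm2$surface_faces_um2)
})

test_that("adding a pore voxel never decreases total pore volume", {
  bone <- array(TRUE, dim = c(12, 12, 12))
  bone[6, 6, 6] <- FALSE
  attr(bone, "voxel_size") <- 9
  v1 <- porosity_report(label_pores(bone, mesh = FALSE))$total_pore_volume_um3
  bone[6, 7, 6] <- FALSE
  v2 <- porosity_report(label_pores(bone, mesh = FALSE))$total_pore_volume_um3
  expect_gte(v2, v1)
})

test_that("porosity aggregates match their definitions on a known cavity", {
  spec <- phantom_spec(nx = 48, ny = 48, nz = 40,
                       cortex_outer_radii = c(190, 170), cortex_thickness = 250,
                       pores = list(pore_sphere(c(24, 24, 20), 54)),
                       psf_sigma = 0, noise_sd = 0)
  ph <- generate_phantom(spec)
  bone <- unclass(ph$truth$label_volume) > 0
  attr(bone, "voxel_size") <- 9
  tab <- label_pores(bone)
  rep <- porosity_report(tab)
  expect_equal(rep$n_closed, 1)
  expect_equal(rep$porosity, ph$truth$true_porosity, tolerance = 1e-12)
  expect_equal(rep$closed_porosity, rep$porosity)
  expect_error(porosity_report(tab, compartment_volume = 0), "positive")
})
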