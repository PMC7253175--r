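#' Specify a synthetic metaphyseal phantom
#'
#' Describes a 3D phantom emulating a maturing metaphysis: an elliptical
#' cortical shell (optionally enclosing a marrow cavity bridged by
#' trabecular struts), an axial low-to-high mineralisation gradient,
#' embedded pores with a low-density remodelling lining, calibration
#' inserts outside the bone, then Gaussian partial-volume blur and additive
#' noise. All geometry is validated to fit the grid at specification time.
#'
#' The mineral gradient is expressed as per-tier weights as a function of
#' the axial fraction `zfrac` in `[0, 1]` (0 = distal/growth-plate end):
#' within each slice, bone voxels are assigned to low/mid/high tiers by
#' angular sector in proportion to the weights, which keeps the per-slice
#' tier fractions exact and deterministic.
#'
#' @param nx,ny,nz Grid extent in voxels (z = axial).
#' @param voxel_size Voxel edge, micrometres (default 9).
#' @param cortex_outer_radii Outer semi-axes of the cortical ellipse in
#'   micrometres, `c(a, b)`, or a function of `zfrac` returning them.
#' @param cortex_thickness Cortical wall thickness, micrometres; a value
#'   at least `min(cortex_outer_radii)` gives a solid (consolidated) rod.
#' @param strut_count,strut_radius Number and radius (um) of axial
#'   trabecular struts bridging the marrow cavity.
#' @param gradient Function `zfrac -> c(low, mid, high)` tier weights
#'   (normalised internally).
#' @param tier_gray Named grayscale means, strictly increasing:
#'   `c(excluded, low, mid, high)`. `excluded` is the non-bone background
#'   (marrow, outside air).
#' @param pore_gray Grayscale inside pores (air; default 0).
#' @param pore_lining Thickness (um) of the low-tier lining shell around
#'   each pore, emulating low-mineralised remodelling surfaces (default 27).
#' @param surface_lining Thickness (um) of the low-tier layer at the
#'   periosteal and endosteal surfaces, emulating the newly-formed
#'   low-mineral bone that lines real cortices (default 27). Struts
#'   thinner than twice this are entirely low density.
#' @param pores List of pore descriptors from [pore_sphere()],
#'   [pore_tube()] or [pore_box()].
#' @param inserts List of calibration inserts, each
#'   `list(density =, gray =, centre_xy =, radius =, z_range =)` (radius in
#'   um); placed outside the bone so they never contaminate ROI statistics.
#' @param reference_slice Growth-plate landmark slice (1-based).
#' @param bone_length Nominal bone length (um) used to derive the default
#'   ROI; `NULL` means the truth ROI covers all slices.
#' @param psf_sigma Gaussian point-spread sigma, voxels (>= 0).
#' @param noise_sd Additive Gaussian noise sd, grayscale units (>= 0).
#' @param bit_depth Grayscale bit depth of the generated volume (8 or 16).
#' @param seed Integer seed for the noise realisation.
#' @param strut_seed Separate seed for strut placement; kept apart from
#'   `seed` so that changing the noise realisation never changes the
#'   geometry or its ground truth.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(nx = 96, ny = 96, nz = 120, voxel_size = 9,
                         cortex_outer_radii = c(360, 324),
                         cortex_thickness = 81,
                         strut_count = 0, strut_radius = 13.5,
                         gradient = function(zfrac)
                           c(low = 0.7 * (1 - zfrac), mid = 0.3, high = 0.7 * zfrac),
                         tier_gray = c(excluded = 0, low = 90, mid = 135, high = 200),
                         pore_gray = 0, pore_lining = 27, surface_lining = 27,
                         pores = list(), inserts = list(),
                         reference_slice = 1, bone_length = NULL,
                         psf_sigma = 1, noise_sd = 3, bit_depth = 8,
                         seed = 1, strut_seed = 42) {
  if (nx < 4 || ny < 4 || nz < 1) stop("grid too small (zero-size or degenerate)")
  if (length(tier_gray) != 4 || any(diff(tier_gray) <= 0))
    stop("tier_gray must be 4 strictly increasing values (excluded, low, mid, high)")
  if (psf_sigma < 0 || noise_sd < 0) stop("psf_sigma and noise_sd must be >= 0")
  radii_fun <- if (is.function(cortex_outer_radii)) cortex_outer_radii
               else function(zfrac) cortex_outer_radii
  vz <- voxel_size
  for (f in c(0, 0.5, 1)) {
    ab <- radii_fun(f)
    if (2 * ab[1] / vz > nx - 2 || 2 * ab[2] / vz > ny - 2)
      stop(sprintf("cortex outer radii (%g, %g) um exceed the grid at zfrac %g",
                   ab[1], ab[2], f))
  }
  for (i in seq_along(pores)) {
    p <- pores[[i]]
    rv <- p$radius / vz
    if (!is.null(p$radius) && rv < 1)
      stop(sprintf("pore %d: radius below one voxel", i))
    ok <- switch(p$shape,
      sphere = all(p$centre - rv >= 1) &&
               all(p$centre + rv <= c(nx, ny, nz)),
      tube   = all(p$centre_xy - rv >= 1) &&
               all(p$centre_xy + rv <= c(nx, ny)) &&
               p$z_range[1] >= 1 && p$z_range[2] <= nz,
      box    = all(p$corner >= 1) &&
               all(p$corner + p$size - 1 <= c(nx, ny, nz)),
      stop(sprintf("pore %d: unknown shape '%s'", i, p$shape)))
    if (!ok) stop(sprintf("pore %d (%s) does not fit inside the grid", i, p$shape))
  }
  for (i in seq_along(inserts)) {
    ins <- inserts[[i]]
    rv <- ins$radius / vz
    if (any(ins$centre_xy - rv < 1) || any(ins$centre_xy + rv > c(nx, ny)) ||
        ins$z_range[1] < 1 || ins$z_range[2] > nz)
      stop(sprintf("calibration insert %d does not fit inside the grid", i))
  }
  structure(list(nx = nx, ny = ny, nz = nz, voxel_size = voxel_size,
                 radii_fun = radii_fun, cortex_thickness = cortex_thickness,
                 strut_count = strut_count, strut_radius = strut_radius,
                 gradient = gradient, tier_gray = tier_gray,
                 pore_gray = pore_gray, pore_lining = pore_lining,
                 surface_lining = surface_lining,
                 pores = pores, inserts = inserts,
                 reference_slice = reference_slice, bone_length = bone_length,
                 psf_sigma = psf_sigma, noise_sd = noise_sd,
                 bit_depth = bit_depth, seed = seed, strut_seed = strut_seed),
            class = "phantom_spec")
}

#' Pore geometry descriptors for [phantom_spec()]
#'
#' `pore_sphere` is a sphere at voxel coordinates `centre = c(x, y, z)`;
#' `pore_tube` an axial cylinder over `z_range`; `pore_box` an axis-aligned
#' box given by its lower corner and size in voxels (useful for exact
#' voxel-count fixtures). Radii in micrometres.
#'
#' @param centre,centre_xy,corner Voxel coordinates.
#' @param radius Radius in micrometres.
#' @param z_range `c(z1, z2)` slice range of a tube.
#' @param size Box size in voxels `c(sx, sy, sz)`.
#' @return A pore descriptor list.
#' @export
pore_sphere <- function(centre, radius)
  list(shape = "sphere", centre = centre, radius = radius)

#' @rdname pore_sphere
#' @export
pore_tube <- function(centre_xy, radius, z_range)
  list(shape = "tube", centre_xy = centre_xy, radius = radius, z_range = z_range)

#' @rdname pore_sphere
#' @export
pore_box <- function(corner, size)
  list(shape = "box", corner = corner, size = size)

# voxel mask of one pore (logical 3D array of the full grid)
pore_mask_of <- function(p, nx, ny, nz, vz, grow_um = 0) {
  X <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  Y <- matrix(seq_len(ny), ny, nx)
  m <- array(FALSE, dim = c(ny, nx, nz))
  if (p$shape == "sphere") {
    rv <- (p$radius + grow_um) / vz
    zs <- max(1, floor(p$centre[3] - rv)):min(nz, ceiling(p$centre[3] + rv))
    for (z in zs) {
      rz2 <- rv^2 - (z - p$centre[3])^2
      if (rz2 < 0) next
      m[, , z] <- (X - p$centre[1])^2 + (Y - p$centre[2])^2 <= rz2
    }
  } else if (p$shape == "tube") {
    rv <- (p$radius + grow_um) / vz
    disc <- (X - p$centre_xy[1])^2 + (Y - p$centre_xy[2])^2 <= rv^2
    for (z in p$z_range[1]:p$z_range[2]) m[, , z] <- disc
  } else {  # box
    g <- round(grow_um / vz)
    xs <- max(1, p$corner[1] - g):min(nx, p$corner[1] + p$size[1] - 1 + g)
    ys <- max(1, p$corner[2] - g):min(ny, p$corner[2] + p$size[2] - 1 + g)
    zs <- max(1, p$corner[3] - g):min(nz, p$corner[3] + p$size[3] - 1 + g)
    m[ys, xs, zs] <- TRUE
  }
  m
}

#' Generate a phantom volume with exact ground truth
#'
#' Builds the tier label volume deterministically from the spec, captures
#' ground truth on it by exact voxel counting (per-slice tier fractions,
#' ROI tier fractions, pore inventory with open/closed status, porosity),
#' and only then applies the point-spread blur and additive noise to
#' produce the measured volume. For a fixed seed the output is fully
#' deterministic.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (grayscale [volume3d()]), `truth`
#'   (a `phantom_truth`: `label_volume`, `per_slice`, `roi_fractions`,
#'   `pore_inventory`, `true_porosity`, `roi`, `insert_points`,
#'   `gray_shift`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  built <- build_labels(spec)
  truth <- capture_truth(built, spec)
  vol <- render_volume(built, spec, gray_shift = 0,
                       seed = spec$seed)
  list(volume = vol, truth = truth, spec = spec)
}

# deterministic label construction (no blur, no noise)
build_labels <- function(spec) {
  nx <- spec$nx; ny <- spec$ny; nz <- spec$nz; vz <- spec$voxel_size
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  X <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  Y <- matrix(seq_len(ny), ny, nx)
  theta_frac <- (atan2(Y - cy, X - cx) / (2 * pi)) %% 1

  # struts are placed once from the seed so labels are seed-stable
  struts <- NULL
  if (spec$strut_count > 0) {
    rng <- local_rng(spec$strut_seed)
    ab0 <- spec$radii_fun(0)
    repeat {
      u <- rng(2 * spec$strut_count)
      ang <- 2 * pi * u[seq_len(spec$strut_count)]
      rad <- sqrt(u[-seq_len(spec$strut_count)])
      sx <- cx + rad * (0.85 * (ab0[1] - spec$cortex_thickness) / vz) * cos(ang)
      sy <- cy + rad * (0.85 * (ab0[2] - spec$cortex_thickness) / vz) * sin(ang)
      break
    }
    struts <- cbind(sx, sy)
  }

  label <- array(0L, dim = c(ny, nx, nz))
  for (z in seq_len(nz)) {
    zf <- if (nz > 1) (z - 1) / (nz - 1) else 0
    ab <- spec$radii_fun(zf) / vz
    outer_e <- ((X - cx) / ab[1])^2 + ((Y - cy) / ab[2])^2 <= 1
    tv <- spec$cortex_thickness / vz
    bone <- outer_e
    if (tv < min(ab)) {
      marrow <- ((X - cx) / (ab[1] - tv))^2 + ((Y - cy) / (ab[2] - tv))^2 <= 1
      bone <- outer_e & !marrow
      if (!is.null(struts)) {
        rv <- spec$strut_radius / vz
        for (s in seq_len(nrow(struts)))
          bone <- bone | (marrow &
            (X - struts[s, 1])^2 + (Y - struts[s, 2])^2 <= rv^2)
      }
    }
    w <- spec$gradient(zf)
    if (any(w < 0)) stop("gradient weights must be non-negative")
    w <- w / sum(w)
    lab <- 1L + findInterval(theta_frac, cumsum(w)[1:2])
    sl <- label[, , z]
    sl[bone] <- lab[bone]
    # graded low-mineral lining at periosteal/endosteal surfaces: the
    # outermost band is low, the next band at most mid, so mineral tiers
    # always change one step at a time across any interface
    slv <- spec$surface_lining / vz
    if (slv > 0) {
      in_shrunk <- function(k) {
        if (any(ab - k * slv <= 0)) return(array(FALSE, dim(X)))
        ((X - cx) / (ab[1] - k * slv))^2 + ((Y - cy) / (ab[2] - k * slv))^2 <= 1
      }
      band1 <- outer_e & !in_shrunk(1)
      band2 <- in_shrunk(1) & !in_shrunk(2)
      if (tv < min(ab)) {
        in_grown <- function(k)
          ((X - cx) / (ab[1] - tv + k * slv))^2 +
            ((Y - cy) / (ab[2] - tv + k * slv))^2 <= 1
        band1 <- band1 | in_grown(1)
        band2 <- band2 | (in_grown(2) & !in_grown(1))
      }
      sel <- band1 & sl > 0L
      sl[sel] <- 1L
      sel <- band2 & sl > 2L
      sl[sel] <- 2L
    }
    label[, , z] <- sl
  }

  pore_mask <- array(FALSE, dim = c(ny, nx, nz))
  for (p in spec$pores) {
    pm <- pore_mask_of(p, nx, ny, nz, vz)
    if (spec$pore_lining > 0) {
      # graded remodelling lining, as at the outer surfaces
      g1 <- pore_mask_of(p, nx, ny, nz, vz, grow_um = spec$pore_lining)
      g2 <- pore_mask_of(p, nx, ny, nz, vz, grow_um = 2 * spec$pore_lining)
      shell1 <- g1 & !pm
      shell2 <- g2 & !g1
      label[shell1 & label > 0L] <- 1L
      sel <- shell2 & label > 2L
      label[sel] <- 2L
    }
    pore_mask <- pore_mask | pm
  }
  label[pore_mask] <- 0L

  insert_mask <- array(0L, dim = c(ny, nx, nz))
  for (i in seq_along(spec$inserts)) {
    ins <- spec$inserts[[i]]
    rv <- ins$radius / vz
    disc <- (X - ins$centre_xy[1])^2 + (Y - ins$centre_xy[2])^2 <= rv^2
    for (z in ins$z_range[1]:ins$z_range[2]) {
      if (any(label[, , z][disc] > 0L))
        stop(sprintf("calibration insert %d overlaps bone", i))
      im <- insert_mask[, , z]; im[disc] <- i; insert_mask[, , z] <- im
    }
  }

  list(label = label, pore_mask = pore_mask, insert_mask = insert_mask)
}

capture_truth <- function(built, spec) {
  label <- built$label
  labels <- structure(label, levels = c("excluded", "low", "mid", "high"),
                      voxel_size = spec$voxel_size, class = "tier_labels")
  bone <- label > 0L
  env <- envelope_mask(bone)
  roi <- if (!is.null(spec$bone_length))
    select_roi(spec$bone_length, spec$voxel_size, spec$reference_slice,
               n_slices_total = spec$nz)
  else
    whole_volume_roi(spec$nz, spec$voxel_size)

  prof <- slice_profile(labels, roi = NULL, envelope = env)
  summ <- roi_summary(labels, roi = roi, envelope = env)
  inv <- tryCatch(
    label_pores(bone, roi = roi, voxel_size = spec$voxel_size,
                envelope = env, mesh = FALSE),
    error = function(e) NULL)
  zr <- roi_slices(roi)
  comp_vox <- sum(env[, , zr])
  pore_vox <- if (is.null(inv)) 0 else sum(inv$voxels)
  ip <- if (length(spec$inserts))
    data.frame(gray = vapply(spec$inserts, `[[`, 0, "gray"),
               density_g_cm3 = vapply(spec$inserts, `[[`, 0, "density"))
  else NULL

  structure(list(label_volume = labels, per_slice = prof,
                 roi_fractions = summ$fractions, roi = roi,
                 pore_inventory = inv,
                 true_porosity = pore_vox / comp_vox,
                 compartment_voxels = comp_vox,
                 insert_points = ip, gray_shift = 0),
            class = "phantom_truth")
}

# an roi_spec that simply covers every slice
whole_volume_roi <- function(nz, voxel_size) {
  structure(list(offset_fraction = 0, length_fraction = 1,
                 reference_slice = 1L, bone_length = nz * voxel_size,
                 voxel_size = voxel_size, start_slice = 1L,
                 n_slices = as.integer(nz)),
            class = "roi_spec")
}

render_volume <- function(built, spec, gray_shift = 0, seed = 1) {
  gray <- spec$tier_gray[built$label + 1L]
  gray <- array(gray, dim = dim(built$label))
  gray[built$pore_mask] <- spec$pore_gray
  for (i in seq_along(spec$inserts))
    gray[built$insert_mask == i] <- spec$inserts[[i]]$gray
  if (spec$psf_sigma > 0)
    gray <- cpp_gaussian_blur(gray, dim(gray), spec$psf_sigma)
  gray <- gray + gray_shift
  if (spec$noise_sd > 0) {
    rng <- local_rng(seed)
    gray <- gray + array(rng(length(gray), sd = spec$noise_sd), dim = dim(gray))
  }
  maxval <- 2^spec$bit_depth - 1
  gray <- round(pmin(pmax(gray, 0), maxval))
  volume3d(array(gray, dim = dim(built$label)), spec$voxel_size,
           "grayscale", bit_depth = spec$bit_depth)
}

# seed-local gaussian/uniform draws that do not disturb the global RNG
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  function(n, sd = NULL) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- if (is.null(sd)) stats::runif(n) else stats::rnorm(n, 0, sd)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
}

#' Generate a cohort of phantoms for threshold derivation
#'
#' Replicates one phantom `n` times with random global grayscale shifts
#' (emulating scan-to-scan brightness variation) and independent noise.
#' The tier labels and truth are captured before any shift or noise, so
#' every member shares the base truth; the applied shift is recorded in
#' each member's truth.
#'
#' @param spec A [phantom_spec()].
#' @param n Cohort size (>= 2).
#' @param gray_shift_sd SD of the per-sample global grayscale shift.
#' @param seed Seed for shifts and noise (defaults to `spec$seed`).
#' @return List of `n` elements, each `list(volume, truth, spec)`.
#' @export
generate_reference_cohort <- function(spec, n, gray_shift_sd = 0, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n < 2) stop("cohort needs n >= 2 (spread statistics are undefined otherwise)")
  built <- build_labels(spec)
  truth <- capture_truth(built, spec)
  rng <- local_rng(seed)
  shifts <- rng(n, sd = gray_shift_sd)
  member_seeds <- floor(rng(n) * 2^30)
  lapply(seq_len(n), function(i) {
    tr <- truth
    tr$gray_shift <- shifts[i]
    list(volume = render_volume(built, spec, gray_shift = shifts[i],
                                seed = member_seeds[i]),
         truth = tr, spec = spec)
  })
}

#' Measure calibration inserts on a generated phantom
#'
#' Returns the measured mean grayscale inside each insert (eroded 2 voxels
#' radially to avoid blurred rims) together with its known density, ready
#' for [fit_calibration()].
#'
#' @param volume The measured phantom [volume3d()].
#' @param spec The [phantom_spec()] it was generated from.
#' @return data.frame with columns `gray_mean`, `density_g_cm3`.
#' @export
measure_inserts <- function(volume, spec) {
  if (!length(spec$inserts)) stop("phantom has no calibration inserts")
  vz <- spec$voxel_size
  X <- matrix(seq_len(spec$nx), spec$ny, spec$nx, byrow = TRUE)
  Y <- matrix(seq_len(spec$ny), spec$ny, spec$nx)
  out <- lapply(spec$inserts, function(ins) {
    rv <- ins$radius / vz - 2
    if (rv < 1) rv <- ins$radius / vz
    disc <- (X - ins$centre_xy[1])^2 + (Y - ins$centre_xy[2])^2 <= rv^2
    zs <- (ins$z_range[1] + 1):(ins$z_range[2] - 1)
    if (length(zs) < 1) zs <- ins$z_range[1]:ins$z_range[2]
    vals <- volume$voxels[, , zs, drop = FALSE][rep(disc, length(zs))]
    data.frame(gray_mean = mean(vals), density_g_cm3 = ins$density)
  })
  do.call(rbind, out)
}

#' Ready-made phantom presets
#'
#' * `"cylinder"`: small noiseless solid rod of uniform mid-density bone —
#'   the minimal single-class fixture.
#' * `"gradient"`: 96 x 96 x 120 metaphysis with marrow cavity, trabecular
#'   struts, a low-to-high axial gradient, one closed and one open pore,
#'   and two calibration inserts; blur 1 voxel, noise sd 3.
#' * `"recovery"`: 200 x 200 x 300 consolidated rod with the axial
#'   gradient, two embedded closed pores giving ~5% porosity of the
#'   metaphyseal ROI, four calibration inserts; blur 1 voxel, noise sd 3.
#'   The tier-gray spacing keeps mode separation / noise >= 10.
#'
#' All presets put the grayscale means on the calibration line
#' `density = 0.01 * gray` so insert-derived calibration recovers the
#' designed densities.
#'
#' @param name Preset name.
#' @param seed Seed override.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = c("cylinder", "gradient", "recovery"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    cylinder = phantom_spec(
      nx = 40, ny = 40, nz = 30, cortex_outer_radii = c(108, 108),
      cortex_thickness = 120,  # >= radius: solid
      gradient = function(zfrac) c(low = 0, mid = 1, high = 0),
      pores = list(), inserts = list(), pore_lining = 0, surface_lining = 0,
      psf_sigma = 0, noise_sd = 0, bone_length = NULL, seed = seed),
    gradient = phantom_spec(
      nx = 96, ny = 96, nz = 120, cortex_outer_radii = c(396, 360),
      cortex_thickness = 153, strut_count = 12, strut_radius = 13.5,
      pores = list(pore_sphere(c(48 + 34, 48, 60), 18),
                   pore_tube(c(48, 48 + 32), 18, c(1, 120))),
      inserts = list(
        list(density = 0.25, gray = 25, centre_xy = c(8, 8), radius = 45,
             z_range = c(1, 6)),
        list(density = 1.25, gray = 125, centre_xy = c(88, 8), radius = 45,
             z_range = c(1, 6))),
      reference_slice = 8, bone_length = 3600,
      psf_sigma = 1, noise_sd = 3, seed = seed),
    recovery = phantom_spec(
      nx = 200, ny = 200, nz = 300, cortex_outer_radii = c(720, 630),
      cortex_thickness = 720,  # solid consolidated rod
      pores = list(pore_sphere(c(100, 100, 170), 315),
                   pore_sphere(c(135, 80, 260), 72)),
      inserts = list(
        list(density = 0.25, gray = 25, centre_xy = c(20, 20), radius = 90,
             z_range = c(1, 8)),
        list(density = 0.75, gray = 75, centre_xy = c(180, 20), radius = 90,
             z_range = c(1, 8)),
        list(density = 1.25, gray = 125, centre_xy = c(20, 180), radius = 90,
             z_range = c(1, 8)),
        list(density = 1.75, gray = 175, centre_xy = c(180, 180), radius = 90,
             z_range = c(1, 8))),
      reference_slice = 1, bone_length = 12000,
      psf_sigma = 1, noise_sd = 3, seed = seed))
}
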