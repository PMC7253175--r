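#' Fit a grayscale-to-density calibration line
#'
#' Micro-CT mineral density is calibrated against phantom inserts of known
#' calcium hydroxyapatite (CaHA) density: an ordinary-least-squares line
#' `density = slope * gray + intercept` through the measured mean grayscale
#' of each insert. Denser material must be brighter, so a non-positive
#' fitted slope is an error.
#'
#' @param gray Numeric vector of insert mean grayscale values, or a
#'   data.frame with columns `gray_mean` and `density_g_cm3`.
#' @param density Known insert densities, g/cm^3 CaHA (omit if `gray` is a
#'   data.frame).
#' @return A `calibration_curve`: slope (g/cm^3 per gray unit), intercept
#'   (g/cm^3), `r_squared`, and the points used.
#' @export
fit_calibration <- function(gray, density = NULL) {
  if (is.data.frame(gray)) {
    density <- gray$density_g_cm3
    gray <- gray$gray_mean
  }
  if (length(gray) < 2L) stop("need at least 2 calibration points")
  if (anyDuplicated(gray)) stop("duplicate grayscale values in calibration points")
  fit <- stats::lm(density ~ gray)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0)
    stop(sprintf("fitted slope %.4g is not positive; points: %s",
                 slope, paste(sprintf("(%g, %g)", gray, density), collapse = " ")))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((density - mean(density))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 points = data.frame(gray_mean = gray, density_g_cm3 = density)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> density = %.6g * gray + %.6g  (r^2 = %.4f, %d points)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Convert grayscale to CaHA density
#'
#' Applies the affine calibration map elementwise. For a [volume3d()] input
#' the result is a density-valued volume; an already-density volume is an
#' error (double calibration).
#'
#' @param x A grayscale `volume3d` or numeric vector.
#' @param curve A `calibration_curve`.
#' @return Density in g/cm^3 CaHA (same shape as input).
#' @export
gray_to_density <- function(x, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (is_volume3d(x)) {
    if (x$value_kind == "density")
      stop("volume is already density-valued; refusing to calibrate twice")
    d <- curve$slope * x$voxels + curve$intercept
    d[d < 0] <- 0  # air can calibrate fractionally below zero; clamp
    return(volume3d(d, x$voxel_size, "density"))
  }
  curve$slope * x + curve$intercept
}

#' Convert CaHA density back to grayscale
#'
#' Inverse of [gray_to_density()]; the calibration slope is guaranteed
#' positive so the inverse always exists.
#'
#' @param x Density value(s), g/cm^3 CaHA.
#' @param curve A `calibration_curve`.
#' @return Grayscale value(s).
#' @export
density_to_gray <- function(x, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  (x - curve$intercept) / curve$slope
}

#' Read calibration points from CSV
#'
#' Expects columns `gray_mean` and `density_g_cm3`.
#' @param path CSV file path.
#' @return A `calibration_curve` from [fit_calibration()].
#' @export
read_calibration_csv <- function(path) {
  fit_calibration(utils::read.csv(path))
}

#' Persist / load a calibration curve as JSON
#' @param curve A `calibration_curve`.
#' @param path JSON file path.
#' @return `write_calibration_json` invisibly returns `path`;
#'   `read_calibration_json` returns the curve.
#' @export
write_calibration_json <- function(curve, path) {
  jsonlite::write_json(list(slope = curve$slope, intercept = curve$intercept,
                            r_squared = curve$r_squared,
                            points = curve$points),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cur <- fit_calibration(j$points)
  cur$slope <- j$slope; cur$intercept <- j$intercept; cur$r_squared <- j$r_squared
  cur
}
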