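#' Grayscale histogram of a volume
#'
#' Histogram convention: 8-bit data get the native 256 unit-width bins
#' `[i, i+1)`, `i = 0..255`, with the integer itself as the bin's moment
#' value; wider or non-integer data get 256 equal-width bins over the
#' observed range with midpoints as moment values. Thresholds derived from
#' a histogram are always reported as the lower edge of the first bin of a
#' class.
#'
#' @param x A grayscale [volume3d()] or numeric vector.
#' @param bins Bin count for non-8-bit data (default 256).
#' @return A `gray_histogram`: `breaks` (length n+1), `counts`, `values`.
#' @export
gray_histogram <- function(x, bins = 256L) {
  if (is_volume3d(x)) {
    stopifnot_volume(x, "grayscale")
    native8 <- x$bit_depth == 8L
    x <- as.numeric(x$voxels)
  } else {
    x <- as.numeric(x)
    native8 <- all(x == round(x)) && min(x) >= 0 && max(x) <= 255
  }
  if (length(x) == 0) stop("empty input: cannot build a histogram")
  if (native8) {
    counts <- tabulate(as.integer(x) + 1L, nbins = 256L)
    h <- list(breaks = 0:256, counts = counts, values = 0:255)
  } else {
    rng <- range(x)
    if (rng[1] == rng[2]) rng[2] <- rng[1] + 1
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
    counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                       nbins = bins)
    h <- list(breaks = breaks, counts = counts,
              values = (breaks[-1] + breaks[-(bins + 1L)]) / 2)
  }
  structure(h, class = "gray_histogram")
}

#' Multi-level Otsu thresholding
#'
#' Finds the strictly increasing (k-1)-tuple of bin boundaries that
#' maximises the between-class variance of the histogram, the multi-class
#' generalisation of Otsu's criterion. Solved exactly by dynamic
#' programming over precomputed cumulative zeroth/first moments, so the
#' result agrees with exhaustive search over all boundary tuples; ties are
#' broken toward the lexicographically smallest tuple. Thresholds are
#' lower-inclusive class floors: class i covers `[t_i, t_{i+1})`.
#'
#' @param x A `gray_histogram` (or anything [gray_histogram()] accepts).
#' @param n_classes Number of classes k (default 4, giving 3 thresholds).
#' @return An `otsu_result`: `thresholds` (grayscale, length k-1),
#'   `between_class_variance`, and the histogram used.
#' @export
multi_otsu <- function(x, n_classes = 4L) {
  h <- if (inherits(x, "gray_histogram")) x else gray_histogram(x)
  k <- as.integer(n_classes)
  if (k < 2L) stop("n_classes must be at least 2")
  n <- length(h$counts)
  if (sum(h$counts) == 0) stop("empty histogram")
  if (sum(h$counts > 0) < k)
    stop(sprintf("histogram has %d non-empty bins; need at least %d for %d classes",
                 sum(h$counts > 0), k, k))

  w <- h$counts / sum(h$counts)
  cw <- c(0, cumsum(w))
  cm <- c(0, cumsum(w * h$values))
  # segment score S[i, j] = (sum of moments in bins i..j)^2 / weight
  W <- outer(cw[-1], cw[-(n + 1)], "-")        # W[j, i] = weight of bins i..j
  M <- outer(cm[-1], cm[-(n + 1)], "-")
  S <- ifelse(W > 0, M^2 / W, -Inf)            # S[j, i], valid for j >= i

  # G[m, j] = best score splitting bins j..n into m classes
  G <- matrix(-Inf, k, n)
  G[1, ] <- S[n, ]
  for (m in 2:k) {
    for (j in 1:(n - m + 1L)) {
      t <- j:(n - m + 1L)
      G[m, j] <- max(S[t, j] + G[m - 1L, t + 1L])
    }
  }
  # forward reconstruction, smallest boundary at each stage
  starts <- integer(k - 1L)
  j <- 1L
  for (m in k:2) {
    t <- j:(n - m + 1L)
    vals <- S[t, j] + G[m - 1L, t + 1L]
    tstar <- t[which(vals == G[m, j])[1]]
    starts[k - m + 1L] <- tstar + 1L  # first bin of the next class
    j <- tstar + 1L
  }
  mu <- cm[n + 1]
  structure(list(thresholds = as.numeric(h$breaks[starts]),
                 between_class_variance = G[k, 1] - mu^2,
                 class_start_bins = starts, histogram = h),
            class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("<otsu_result> %d thresholds: %s | between-class variance %.6g\n",
              length(x$thresholds), paste(signif(x$thresholds, 6), collapse = ", "),
              x$between_class_variance))
  invisible(x)
}

#' Percent spread of per-sample thresholds
#'
#' Range as a percentage of the midpoint, `100 * (max - min) / ((max + min) / 2)`,
#' the consistency figure reported for cohort-derived segmentation
#' thresholds.
#'
#' @param x Numeric vector of per-sample threshold values (or its min and max).
#' @return Percent spread (>= 0).
#' @export
percent_spread <- function(x) {
  lo <- min(x); hi <- max(x)
  100 * (hi - lo) / ((hi + lo) / 2)
}

#' Mineral-density tier boundaries
#'
#' Orders voxels into four mineral-density classes on the CaHA scale:
#' excluded below `low`, then low `[low, mid)`, mid `[mid, high)` and high
#' `>= high` (all boundaries lower-inclusive). Defaults are the reference
#' metaphyseal boundaries 0.632 / 1.143 / 1.528 g/cm^3 CaHA;
#' [archive_tiers()] gives the variant used for archive scans acquired
#' under different settings (0.565 / 1.036 / 1.432).
#'
#' @param low,mid,high Tier floors in g/cm^3 CaHA, strictly increasing.
#' @param gray Optional grayscale equivalents (same order), e.g. from a
#'   calibration curve.
#' @param provenance Optional list describing how the boundaries were
#'   derived (cohort id, per-sample thresholds, spread).
#' @return A `density_tiers` object.
#' @export
density_tiers <- function(low = 0.632, mid = 1.143, high = 1.528,
                          gray = NULL, provenance = NULL) {
  b <- c(low = low, mid = mid, high = high)
  if (any(diff(b) <= 0)) stop("tier boundaries must be strictly increasing")
  if (!is.null(gray) && any(diff(gray) <= 0))
    stop("grayscale equivalents must be strictly increasing")
  structure(list(boundaries = b, gray = gray, provenance = provenance),
            class = "density_tiers")
}

#' @rdname density_tiers
#' @export
archive_tiers <- function() density_tiers(0.565, 1.036, 1.432)

#' @export
print.density_tiers <- function(x, ...) {
  b <- x$boundaries
  cat(sprintf("<density_tiers> excluded < %g | low [%g, %g) | mid [%g, %g) | high >= %g  (g/cm^3 CaHA)\n",
              b[1], b[1], b[2], b[2], b[3], b[3]))
  if (!is.null(x$provenance$spread)) {
    s <- x$provenance$spread
    cat(sprintf("  cohort n = %d; per-threshold spread %% : %s\n",
                x$provenance$n_samples, paste(signif(s, 3), collapse = ", ")))
  }
  invisible(x)
}

#' Derive consensus tier boundaries from a reference cohort
#'
#' Runs 4-level Otsu thresholding per sample on the region-of-interest
#' grayscale histogram, averages the per-sample thresholds into a consensus
#' boundary set, reports their consistency as percent spread
#' (range/midpoint, see [percent_spread()]), and converts the consensus to
#' g/cm^3 CaHA via the calibration curve. Per-sample thresholds are kept
#' for audit. A pooled mode (single histogram over all samples) is
#' available behind `mode = "pooled"`.
#'
#' @param cohort List of grayscale [volume3d()] objects sharing one
#'   calibration.
#' @param roi Optional `roi_spec`; if given, only ROI slices enter the
#'   histogram.
#' @param calibration A `calibration_curve`.
#' @param n_classes Otsu class count (default 4).
#' @param mode `"per_sample"` (average per-sample thresholds, default) or
#'   `"pooled"` (one histogram across the cohort).
#' @return A [density_tiers()] whose provenance records per-sample
#'   thresholds (grayscale), consensus, and spread.
#' @export
derive_reference_thresholds <- function(cohort, roi = NULL, calibration,
                                        n_classes = 4L,
                                        mode = c("per_sample", "pooled")) {
  mode <- match.arg(mode)
  if (length(cohort) < 2L) stop("need a cohort of at least 2 samples")
  grab <- function(v) {
    stopifnot_volume(v, "grayscale")
    if (is.null(roi)) v$voxels else v$voxels[, , roi_slices(roi)]
  }
  per_sample <- matrix(NA_real_, length(cohort), n_classes - 1L)
  for (i in seq_along(cohort)) {
    res <- tryCatch(multi_otsu(gray_histogram(grab(cohort[[i]])), n_classes),
                    error = function(e)
                      stop(sprintf("sample %d failed thresholding: %s", i,
                                   conditionMessage(e))))
    per_sample[i, ] <- res$thresholds
  }
  consensus <- if (mode == "per_sample") {
    colMeans(per_sample)
  } else {
    multi_otsu(gray_histogram(unlist(lapply(cohort, grab))), n_classes)$thresholds
  }
  spread <- apply(per_sample, 2, percent_spread)
  dens <- gray_to_density(consensus, calibration)
  density_tiers(dens[1], dens[2], dens[3], gray = consensus,
                provenance = list(n_samples = length(cohort), mode = mode,
                                  per_sample_thresholds = per_sample,
                                  consensus_gray = consensus, spread = spread))
}

#' Classify voxels into density tiers
#'
#' Assigns each voxel of a calibrated volume to excluded (0), low (1),
#' mid (2) or high (3) by the lower-inclusive tier boundaries: a density
#' exactly at a boundary belongs to the tier above it.
#'
#' @param volume A density-valued [volume3d()] (grayscale input is an
#'   error: calibrate first).
#' @param tiers A [density_tiers()].
#' @return A `tier_labels` integer 3D array (0..3) with attributes
#'   `levels` and `voxel_size`.
#' @export
classify_voxels <- function(volume, tiers) {
  stopifnot_volume(volume, "density")
  stopifnot(inherits(tiers, "density_tiers"))
  lab <- findInterval(volume$voxels, tiers$boundaries)
  lab <- array(as.integer(lab), dim = dim(volume$voxels))
  structure(lab, levels = c("excluded", "low", "mid", "high"),
            voxel_size = volume$voxel_size, class = "tier_labels")
}

tier_names <- function() c("low", "mid", "high")

#' Persist tier boundaries as JSON (both unit systems and provenance)
#' @param tiers A `density_tiers`.
#' @param path JSON file path.
#' @return `write_tiers_json` invisibly returns `path`; `read_tiers_json`
#'   the tiers.
#' @export
write_tiers_json <- function(tiers, path) {
  p <- tiers$provenance
  if (!is.null(p$per_sample_thresholds))
    p$per_sample_thresholds <- as.data.frame(p$per_sample_thresholds)
  jsonlite::write_json(list(boundaries_g_cm3 = as.list(tiers$boundaries),
                            gray = tiers$gray, provenance = p),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tiers_json
#' @export
read_tiers_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  density_tiers(j$boundaries_g_cm3$low, j$boundaries_g_cm3$mid,
                j$boundaries_g_cm3$high, gray = j$gray, provenance = j$provenance)
}
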