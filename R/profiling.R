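#' Per-slice density-tier profile
#'
#' For each z-slice of the region of interest, computes the filled
#' cross-sectional (periosteal envelope) area and each tier's bone area as
#' a percentage of it — the slice-by-slice view of cortical maturation
#' from the growth plate toward the diaphysis. Slices with zero
#' cross-sectional area get `NA` percentages (flagged, never zero, so they
#' cannot bias group means).
#'
#' @param labels A `tier_labels` array from [classify_voxels()].
#' @param roi Optional `roi_spec`; default all slices.
#' @param envelope Optional 3D logical envelope (from [envelope_mask()] on
#'   the bone mask); derived from `labels > 0` when missing.
#' @param sample_id Optional id recorded in the output.
#' @return A `slice_profile` data.frame, one row per slice x tier
#'   (excluded/low/mid/high): `slice`, `distance_um` (from the reference
#'   slice), `cross_section_um2`, `tier`, `area_um2`, `percent`.
#' @export
slice_profile <- function(labels, roi = NULL, envelope = NULL, sample_id = NA_character_) {
  stopifnot(inherits(labels, "tier_labels"))
  vz <- attr(labels, "voxel_size")
  if (is.null(envelope)) envelope <- envelope_mask(unclass(labels) > 0L)
  zr <- if (is.null(roi)) seq_len(dim(labels)[3]) else roi_slices(roi)
  ref <- if (is.null(roi)) 1L else roi$reference_slice
  lv <- c("excluded", "low", "mid", "high")

  rows <- lapply(zr, function(z) {
    env <- envelope[, , z]
    lab <- unclass(labels)[, , z]
    env_n <- sum(env)
    counts <- vapply(0:3, function(t) sum(lab[env] == t), 0)
    pct <- if (env_n > 0) 100 * counts / env_n else rep(NA_real_, 4)
    data.frame(slice = z, distance_um = (z - ref) * vz,
               cross_section_um2 = env_n * vz^2,
               tier = factor(lv, levels = lv),
               area_um2 = counts * vz^2, percent = pct)
  })
  out <- do.call(rbind, rows)
  out$sample_id <- sample_id
  attr(out, "voxel_size") <- vz
  attr(out, "empty_slices") <- zr[vapply(zr, function(z) !any(envelope[, , z]), TRUE)]
  class(out) <- c("slice_profile", "data.frame")
  out
}

#' Whole-ROI density-tier summary
#'
#' Tier bone volumes as fractions of the total metaphyseal (envelope)
#' volume over the region of interest. The denominator is the stacked
#' filled cross-section, so fractions are comparable between porous and
#' consolidated cortices.
#'
#' @inheritParams slice_profile
#' @param roi A `roi_spec` (required).
#' @return A `roi_summary`: `table` (tier, volume_um3, fraction),
#'   `fractions` (named vector low/mid/high/bone), `roi_volume_um3`,
#'   `sample_id`.
#' @export
roi_summary <- function(labels, roi, envelope = NULL, sample_id = NA_character_) {
  stopifnot(inherits(labels, "tier_labels"))
  vz <- attr(labels, "voxel_size")
  if (is.null(envelope)) envelope <- envelope_mask(unclass(labels) > 0L)
  zr <- roi_slices(roi)
  env <- envelope[, , zr, drop = FALSE]
  lab <- unclass(labels)[, , zr, drop = FALSE]
  env_n <- sum(env)
  if (env_n == 0) stop("ROI has zero cross-sectional area on every slice")
  counts <- vapply(0:3, function(t) sum(lab[env] == t), 0)
  lv <- c("excluded", "low", "mid", "high")
  fractions <- counts / env_n
  names(fractions) <- lv
  out <- list(table = data.frame(tier = factor(lv, levels = lv),
                                 volume_um3 = counts * vz^3,
                                 fraction = fractions),
              fractions = c(fractions[c("low", "mid", "high")],
                            bone = unname(sum(fractions[c("low", "mid", "high")]))),
              roi_volume_um3 = env_n * vz^3,
              voxel_size = vz, sample_id = sample_id)
  class(out) <- "roi_summary"
  out
}

#' @export
print.roi_summary <- function(x, ...) {
  cat(sprintf("<roi_summary> ROI volume %.4g um^3 | low %.2f%% mid %.2f%% high %.2f%% (bone %.2f%%)\n",
              x$roi_volume_um3, 100 * x$fractions["low"], 100 * x$fractions["mid"],
              100 * x$fractions["high"], 100 * x$fractions["bone"]))
  invisible(x)
}

#' Default tier palette for pseudocolour export
#'
#' Colour-blind-safe mapping: excluded near-black, low blue, mid amber,
#' high vermilion.
#' @return Named character vector of hex colours.
#' @export
tier_palette <- function() {
  c(excluded = "#1A1A1A", low = "#0072B2", mid = "#E69F00", high = "#D55E00")
}

#' Pseudocolour a label slice
#'
#' Exact colour lookup from tier label to palette entry; the mapping is
#' bijective so labels can be recovered from the image.
#'
#' @param label_slice 2D integer matrix of labels 0..3.
#' @param palette Named colours for every tier (see [tier_palette()]).
#' @return `h x w x 3` numeric array in `[0, 1]`.
#' @export
pseudocolour_slice <- function(label_slice, palette = tier_palette()) {
  lv <- c("excluded", "low", "mid", "high")
  if (!all(lv %in% names(palette)))
    stop("palette is missing tiers: ", paste(setdiff(lv, names(palette)), collapse = ", "))
  rgb <- grDevices::col2rgb(palette[lv]) / 255
  out <- array(0, dim = c(dim(label_slice), 3))
  for (ch in 1:3)
    out[, , ch] <- matrix(rgb[ch, label_slice + 1L], nrow(label_slice))
  out
}

#' Recover labels from a pseudocoloured slice
#' @param img `h x w x 3` array produced by [pseudocolour_slice()].
#' @param palette The palette used.
#' @return 2D integer matrix of labels 0..3.
#' @export
unpseudocolour_slice <- function(img, palette = tier_palette()) {
  lv <- c("excluded", "low", "mid", "high")
  rgb <- round(grDevices::col2rgb(palette[lv]))  # 0..255
  key <- rgb[1, ] * 65536 + rgb[2, ] * 256 + rgb[3, ]
  obs <- round(img[, , 1] * 255) * 65536 + round(img[, , 2] * 255) * 256 +
    round(img[, , 3] * 255)
  lab <- match(obs, key) - 1L
  if (any(is.na(lab))) stop("image contains colours not in the palette")
  matrix(lab, dim(img)[1])
}

#' Export a pseudocoloured PNG stack
#'
#' One RGB PNG per slice plus the palette as JSON.
#'
#' @param labels A `tier_labels` array.
#' @param dir Output directory.
#' @param palette Tier colours.
#' @param slices Slice subset (default all).
#' @return Invisibly, the written file paths.
#' @export
pseudocolour_export <- function(labels, dir, palette = tier_palette(), slices = NULL) {
  stopifnot(inherits(labels, "tier_labels"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(slices)) slices <- seq_len(dim(labels)[3])
  paths <- character(0)
  for (z in slices) {
    p <- file.path(dir, sprintf("slice_%03d.png", z - 1))
    png::writePNG(pseudocolour_slice(unclass(labels)[, , z], palette), p)
    paths <- c(paths, p)
  }
  jsonlite::write_json(as.list(palette), file.path(dir, "palette.json"),
                       auto_unbox = TRUE)
  invisible(c(paths, file.path(dir, "palette.json")))
}

#' Write a slice profile / ROI summary as tidy CSV
#' @param x A `slice_profile` or `roi_summary`.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_profile_csv <- function(x, path) {
  if (inherits(x, "roi_summary")) {
    df <- x$table
    df$sample_id <- x$sample_id
    df$roi_volume_um3 <- x$roi_volume_um3
  } else df <- as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
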