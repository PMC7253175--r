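#' Place an analysis region as fractions of bone length
#'
#' Regions of interest are anchored at a user-supplied growth-plate
#' reference slice and placed as fractions of total bone length, following
#' the standard metaphyseal protocol: offset 7.5% of bone length from the
#' growth plate, extent 15% of bone length (diaphyseal variant: offset 30%).
#' Conversion from micrometres to slices rounds half-away-from-zero.
#'
#' Slices are 1-based: `start_slice` is the first slice of the region and
#' `reference_slice` the growth-plate landmark itself.
#'
#' @param bone_length Total bone length in micrometres.
#' @param voxel_size Voxel edge in micrometres.
#' @param reference_slice 1-based z index of the growth-plate landmark.
#' @param offset_fraction Offset from the reference as a fraction of bone
#'   length (default 0.075; use 0.30 for the diaphysis).
#' @param length_fraction Region extent as a fraction of bone length
#'   (default 0.15).
#' @param n_slices_total Optional z extent of the target volume; if given,
#'   a region overrunning it is an error reporting the overrun.
#' @return A `roi_spec` with derived `start_slice` and `n_slices`.
#' @export
select_roi <- function(bone_length, voxel_size, reference_slice,
                       offset_fraction = 0.075, length_fraction = 0.15,
                       n_slices_total = NULL) {
  if (offset_fraction < 0 || length_fraction <= 0)
    stop("offset_fraction must be >= 0 and length_fraction > 0")
  if (offset_fraction + length_fraction > 1)
    stop("offset_fraction + length_fraction must not exceed 1")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (reference_slice < 1) stop("reference_slice must be >= 1 (1-based)")

  start_slice <- reference_slice + round_half_away(offset_fraction * bone_length / voxel_size)
  n <- round_half_away(length_fraction * bone_length / voxel_size)
  if (!is.null(n_slices_total)) {
    over <- start_slice + n - 1L - n_slices_total
    if (over > 0)
      stop(sprintf("ROI overruns the volume by %d slice(s)", over))
  }
  structure(list(offset_fraction = offset_fraction,
                 length_fraction = length_fraction,
                 reference_slice = as.integer(reference_slice),
                 bone_length = bone_length, voxel_size = voxel_size,
                 start_slice = as.integer(start_slice), n_slices = as.integer(n)),
            class = "roi_spec")
}

# round half away from zero (R's round() is round-half-even)
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> slices %d..%d (n = %d) | offset %.3g, length %.3g of bone length %g um @ %g um/slice\n",
              x$start_slice, x$start_slice + x$n_slices - 1L, x$n_slices,
              x$offset_fraction, x$length_fraction, x$bone_length, x$voxel_size))
  invisible(x)
}

#' z indices covered by a region of interest
#' @param roi A `roi_spec`.
#' @return Integer vector of 1-based slice indices.
#' @export
roi_slices <- function(roi) seq(roi$start_slice, length.out = roi$n_slices)

#' Persist / load an ROI spec as JSON
#' @param roi A `roi_spec`.
#' @param path JSON file path.
#' @return `write_roi_json` invisibly returns `path`; `read_roi_json` the spec.
#' @export
write_roi_json <- function(roi, path) {
  jsonlite::write_json(unclass(roi), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  select_roi(j$bone_length, j$voxel_size, j$reference_slice,
             j$offset_fraction, j$length_fraction)
}

#' Filled cross-sectional envelope of a 2D bone slice
#'
#' The "total cross-sectional area" of a slice is the periosteal envelope:
#' bone plus every cavity fully enclosed by bone in 2D (marrow space,
#' intracortical pores). Computed by flood-filling the background from the
#' slice border (4-connectivity): anything not reached and not bone is an
#' enclosed cavity and gets filled. Disjoint bone islands are each filled
#' without bridging. Idempotent; an empty slice yields an empty mask.
#'
#' @param bone_slice 2D logical matrix (TRUE = bone).
#' @return 2D logical matrix of the filled envelope.
#' @export
cross_section_mask <- function(bone_slice) {
  if (!is.matrix(bone_slice)) stop("`bone_slice` must be a 2D matrix")
  m <- bone_slice > 0
  if (!any(m)) return(m)
  bg <- cpp_label_components(array(!m, dim = c(dim(m), 1L)),
                             as.integer(c(dim(m), 1L)), 6L)
  bg <- bg[, , 1]
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels != 0]
  outside <- array(bg %in% border_labels, dim = dim(bg))
  m | (!m & !outside)
}

#' Filled envelope of every slice of a 3D bone mask
#'
#' Applies [cross_section_mask()] slice-by-slice; the stacked result is the
#' compartment used as the denominator for tier fractions and porosity.
#'
#' @param bone_mask 3D logical array (TRUE = bone).
#' @return 3D logical array of per-slice filled envelopes.
#' @export
envelope_mask <- function(bone_mask) {
  stopifnot(length(dim(bone_mask)) == 3L)
  out <- bone_mask
  for (z in seq_len(dim(bone_mask)[3]))
    out[, , z] <- cross_section_mask(bone_mask[, , z])
  out
}
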