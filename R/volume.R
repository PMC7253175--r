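#' 3D micro-CT volume container
#'
#' A `volume3d` holds a 3D voxel grid with isotropic voxel size and a value
#' kind: raw scanner `"grayscale"` or calibrated `"density"` in g/cm^3
#' calcium hydroxyapatite (CaHA). The array is indexed `[y, x, z]`; z = 1 is
#' the distal (growth-plate) end and z increases toward the diaphysis.
#'
#' @param voxels 3D numeric array, dim `c(ny, nx, nz)`.
#' @param voxel_size Edge length of a voxel in micrometres (isotropic).
#' @param value_kind `"grayscale"` or `"density"`.
#' @param bit_depth For grayscale volumes, 8 or 16; ignored for density.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(voxels, voxel_size = 9, value_kind = c("grayscale", "density"),
                     bit_depth = NULL) {
  value_kind <- match.arg(value_kind)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array (ny, nx, nz)")
  if (any(dim(voxels) == 0L)) stop("volume grid must be non-empty")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (micrometres)")
  if (value_kind == "density") {
    if (any(!is.finite(voxels))) stop("density volumes must be finite")
    if (any(voxels < 0)) stop("density volumes must be non-negative")
    bit_depth <- NULL
  } else {
    if (is.null(bit_depth)) bit_depth <- if (max(voxels) > 255) 16L else 8L
    bit_depth <- as.integer(bit_depth)
    if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  }
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 value_kind = value_kind, bit_depth = bit_depth),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume3d> %d x %d x %d voxels (ny x nx x nz), %g um/voxel, %s%s\n",
              d[1], d[2], d[3], x$voxel_size, x$value_kind,
              if (x$value_kind == "grayscale") sprintf(" (%d-bit)", x$bit_depth) else ""))
  cat(sprintf("  value range [%g, %g]; z = 1 is the distal (growth-plate) end\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$voxels)

#' Number of z-slices of a volume
#' @param volume A `volume3d`.
#' @return Integer slice count.
#' @export
n_slices <- function(volume) dim(volume$voxels)[3]

is_volume3d <- function(x) inherits(x, "volume3d")

stopifnot_volume <- function(x, kind = NULL) {
  if (!is_volume3d(x)) stop("expected a `volume3d` object")
  if (!is.null(kind) && x$value_kind != kind)
    stop(sprintf("expected a %s-valued volume, got %s", kind, x$value_kind))
  invisible(x)
}
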