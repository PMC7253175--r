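#' Write a volume as a TIFF stack with a JSON sidecar
#'
#' Grayscale volumes are written losslessly at their native bit depth (8 or
#' 16); density volumes are written as 32-bit float TIFF. Geometry metadata
#' (voxel size, value kind, axis convention) goes into a JSON sidecar next
#' to the stack, never into TIFF tags.
#'
#' @param volume A [volume3d()].
#' @param path Output path: a `.tif`/`.tiff` file (multipage) or a directory
#'   (one single-page TIFF per slice, `slice_000.tif`, `slice_001.tif`, ...).
#' @param sidecar Path of the JSON sidecar; defaults to `<path>.json` for a
#'   multipage stack and `<path>/volume.json` for a directory.
#' @return Invisibly, the sidecar path.
#' @export
write_stack <- function(volume, path, sidecar = NULL) {
  stopifnot_volume(volume)
  v <- volume$voxels
  nz <- dim(v)[3]
  multipage <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (is.null(sidecar))
    sidecar <- if (multipage) paste0(path, ".json") else file.path(path, "volume.json")

  scale <- 1
  if (volume$value_kind == "grayscale") {
    maxval <- 2^volume$bit_depth - 1
    if (any(v < 0) || any(v > maxval) || any(v != round(v)))
      stop(sprintf("grayscale voxels must be integers in [0, %d]", maxval))
    pages <- lapply(seq_len(nz), function(z) v[, , z] / maxval)
    bits <- volume$bit_depth
  } else {
    # float TIFF samples must sit in [0, 1]; the scale goes in the sidecar
    scale <- max(1, max(v))
    pages <- lapply(seq_len(nz), function(z) v[, , z] / scale)
    bits <- 32L
  }

  if (multipage) {
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (z in seq_len(nz))
      tiff::writeTIFF(pages[[z]], file.path(path, sprintf("slice_%03d.tif", z - 1)),
                      bits.per.sample = bits)
  }
  meta <- list(voxel_size_um = volume$voxel_size, value_kind = volume$value_kind,
               axis = "z=distal->proximal", n_slices = nz)
  if (volume$value_kind == "grayscale") meta$bit_depth <- volume$bit_depth
  else meta$density_scale <- scale
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a volume from a TIFF stack and its JSON sidecar
#'
#' Slice order is page order for a multipage stack and lexicographic file
#' order for a per-slice directory, in both cases increasing z. Voxel size
#' must come from the sidecar; there is no silent default.
#'
#' @param path Multipage TIFF file or directory of single-page TIFFs.
#' @param sidecar JSON sidecar path; defaults as in [write_stack()].
#' @return A [volume3d()].
#' @export
read_stack <- function(path, sidecar = NULL) {
  multipage <- !dir.exists(path)
  if (is.null(sidecar))
    sidecar <- if (multipage) paste0(path, ".json") else file.path(path, "volume.json")
  if (!file.exists(sidecar))
    stop("missing sidecar `", sidecar, "`: voxel size must be provided, not defaulted")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$voxel_size_um)) stop("sidecar lacks `voxel_size_um`")
  if (meta$voxel_size_um <= 0) stop("sidecar voxel_size_um must be positive")
  if (is.null(meta$value_kind)) stop("sidecar lacks `value_kind`")

  if (multipage) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  } else {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (length(files) == 0) stop("no TIFF slices found in `", path, "`")
    pages <- lapply(files, tiff::readTIFF, info = TRUE)
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("inconsistent slice dimensions across the stack")

  nz <- length(pages)
  v <- array(0, dim = c(dims[1, 1], dims[2, 1], nz))
  if (meta$value_kind == "grayscale") {
    bits <- attr(pages[[1]], "bits.per.sample")
    if (is.null(bits)) bits <- meta$bit_depth
    if (is.null(bits)) stop("cannot determine grayscale bit depth")
    maxval <- 2^bits - 1
    for (z in seq_len(nz)) v[, , z] <- round(pages[[z]] * maxval)
    volume3d(v, meta$voxel_size_um, "grayscale", bit_depth = bits)
  } else {
    scale <- meta$density_scale %||% 1
    for (z in seq_len(nz)) v[, , z] <- pages[[z]] * scale
    volume3d(v, meta$voxel_size_um, "density")
  }
}
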