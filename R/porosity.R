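#' Global bone mask from a calibrated volume
#'
#' A voxel is bone iff its density is at least `min_density` (lower
#' inclusive). The default 0.238 g/cm^3 CaHA is the standard global
#' threshold for porosity analysis; tier analysis of cortical bone uses
#' 0.632 as its lowest tier floor instead.
#'
#' @param volume A density-valued [volume3d()].
#' @param min_density Bone threshold, g/cm^3 CaHA (default 0.238).
#' @return 3D logical array with a `voxel_size` attribute.
#' @export
bone_mask <- function(volume, min_density = 0.238) {
  stopifnot_volume(volume, "density")
  m <- volume$voxels >= min_density
  attr(m, "voxel_size") <- volume$voxel_size
  m
}

#' Pore volume, surface area and SA:V of one voxel component
#'
#' Volume is exact voxel counting. Two surfaces are reported: the
#' voxel-face count (exact for the digitised shape, but overestimating
#' smooth surfaces by about 1.5x) and an iso-surface mesh (marching
#' tetrahedra at level 0.5 on the component lightly smoothed with a
#' Gaussian of `mesh_sigma` voxels, which tracks smooth surfaces closely).
#' A component so small that smoothing leaves nothing above the level is
#' meshed unsmoothed. SA:V uses the mesh surface.
#'
#' @param mask 3D logical array containing a single pore component.
#' @param voxel_size Voxel edge, micrometres.
#' @param mesh_sigma Smoothing sigma (voxels) before meshing (default 0.8).
#' @return List: `volume_um3`, `surface_mesh_um2`, `surface_faces_um2`,
#'   `sav_um_inv` (mesh-based), `sav_faces_um_inv`.
#' @export
pore_metrics <- function(mask, voxel_size, mesh_sigma = 0.8) {
  if (!any(mask)) stop("empty voxel set")
  n <- sum(mask)
  volume <- n * voxel_size^3
  faces <- exposed_faces(mask)

  pad <- as.integer(ceiling(4 * mesh_sigma) + 1L)
  d <- dim(mask)
  field <- array(0, dim = d + 2L * pad)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask)
  sm <- cpp_gaussian_blur(field, dim(field), mesh_sigma)
  if (max(sm) <= 0.5) sm <- field  # too small to survive smoothing
  area_vox2 <- cpp_mesh_area(sm, dim(sm), 0.5)

  list(volume_um3 = volume,
       surface_mesh_um2 = area_vox2 * voxel_size^2,
       surface_faces_um2 = faces * voxel_size^2,
       sav_um_inv = area_vox2 * voxel_size^2 / volume,
       sav_faces_um_inv = faces * voxel_size^2 / volume)
}

# number of exposed voxel faces of a logical component
exposed_faces <- function(mask) {
  d <- dim(mask)
  n <- sum(mask)
  internal <- 0L
  if (d[1] > 1) internal <- internal + sum(mask[-1, , ] & mask[-d[1], , ])
  if (d[2] > 1) internal <- internal + sum(mask[, -1, ] & mask[, -d[2], ])
  if (d[3] > 1) internal <- internal + sum(mask[, , -1] & mask[, , -d[3]])
  6L * n - 2L * internal
}

#' Label pores and build a per-pore inventory
#'
#' The cortical compartment is the per-slice filled envelope of the bone
#' mask stacked in 3D; pore voxels are compartment voxels that are not
#' bone. Pores are 6-connected components (bone is implicitly
#' 26-connected, the complementary connectivity). A pore is open if any of
#' its voxels lies on the first or last slice of the measurement region or
#' touches (6-adjacency) a voxel outside the compartment; otherwise it is
#' closed. Pores smaller than `detection_floor` are flagged `at_limit`
#' rather than dropped.
#'
#' @param bone 3D logical bone mask (needs a `voxel_size` attribute or an
#'   explicit `voxel_size`).
#' @param roi Optional `roi_spec` restricting the measurement region along z.
#' @param voxel_size Voxel edge, micrometres.
#' @param envelope Optional precomputed envelope (full-volume extent).
#' @param mesh Compute mesh surfaces (set `FALSE` to skip, e.g. for truth
#'   capture by pure voxel counting).
#' @param detection_floor Volume (um^3) below which a pore is flagged
#'   `at_limit` (default 5000, the practical detection floor at 9 um).
#' @return A `pore_table` data.frame: `id`, `voxels`, `volume_um3`,
#'   `surface_mesh_um2`, `surface_faces_um2`, `sav_um_inv`, `status`
#'   (open/closed), `at_limit` and bounding box columns; attributes
#'   `compartment_volume_um3`, `voxel_size`, `roi_slices`.
#' @export
label_pores <- function(bone, roi = NULL, voxel_size = attr(bone, "voxel_size"),
                        envelope = NULL, mesh = TRUE, detection_floor = 5000) {
  stopifnot(length(dim(bone)) == 3L)
  if (is.null(voxel_size)) stop("voxel_size is required")
  if (!any(bone)) stop("empty bone mask: no compartment definable")
  if (is.null(envelope)) envelope <- envelope_mask(bone)
  zr <- if (is.null(roi)) seq_len(dim(bone)[3]) else roi_slices(roi)
  env <- envelope[, , zr, drop = FALSE]
  bn <- bone[, , zr, drop = FALSE]
  pore <- env & !bn
  comp_vol <- sum(env) * voxel_size^3

  empty <- data.frame(id = integer(0), voxels = integer(0),
                      volume_um3 = numeric(0), surface_mesh_um2 = numeric(0),
                      surface_faces_um2 = numeric(0), sav_um_inv = numeric(0),
                      status = character(0), at_limit = logical(0))
  if (!any(pore)) {
    return(structure(empty, compartment_volume_um3 = comp_vol,
                     voxel_size = voxel_size, roi_slices = zr,
                     class = c("pore_table", "data.frame")))
  }

  d <- dim(pore)
  cc <- cpp_label_components(pore, as.integer(d), 6L)
  ncomp <- attr(cc, "n_components")

  # open rule part 1: presence on the region's top/bottom slice
  open_ids <- unique(c(cc[, , 1], cc[, , d[3]]))
  # part 2: 6-adjacency to a voxel outside the compartment (incl. grid edge)
  outside <- !env
  touch <- function(ids) unique(ids[ids != 0])
  if (d[1] > 1) {
    open_ids <- c(open_ids, touch(cc[-1, , ][outside[-d[1], , ]]),
                  touch(cc[-d[1], , ][outside[-1, , ]]))
  }
  if (d[2] > 1) {
    open_ids <- c(open_ids, touch(cc[, -1, ][outside[, -d[2], ]]),
                  touch(cc[, -d[2], ][outside[, -1, ]]))
  }
  if (d[3] > 1) {
    open_ids <- c(open_ids, touch(cc[, , -1][outside[, , -d[3]]]),
                  touch(cc[, , -d[3]][outside[, , -1]]))
  }
  open_ids <- c(open_ids, touch(c(cc[1, , ], cc[d[1], , ],
                                  cc[, 1, ], cc[, d[2], ])))
  open_ids <- unique(open_ids[open_ids != 0])

  idx <- which(cc > 0)
  lab <- cc[idx]
  ay <- (idx - 1) %% d[1] + 1
  ax <- ((idx - 1) %/% d[1]) %% d[2] + 1
  az <- (idx - 1) %/% (d[1] * d[2]) + 1
  by_id <- split(seq_along(idx), lab)

  rows <- lapply(seq_len(ncomp), function(i) {
    sel <- by_id[[as.character(i)]]
    ys <- ay[sel]; xs <- ax[sel]; zs <- az[sel]
    bb <- c(min(xs), max(xs), min(ys), max(ys), min(zs), max(zs))
    sub <- array(FALSE, dim = c(bb[4] - bb[3] + 1L, bb[2] - bb[1] + 1L,
                                bb[6] - bb[5] + 1L))
    sub[cbind(ys - bb[3] + 1L, xs - bb[1] + 1L, zs - bb[5] + 1L)] <- TRUE
    pm <- if (mesh) pore_metrics(sub, voxel_size)
          else {
            f <- exposed_faces(sub)
            list(volume_um3 = length(sel) * voxel_size^3,
                 surface_mesh_um2 = NA_real_,
                 surface_faces_um2 = f * voxel_size^2,
                 sav_um_inv = NA_real_)
          }
    data.frame(id = i, voxels = length(sel), volume_um3 = pm$volume_um3,
               surface_mesh_um2 = pm$surface_mesh_um2,
               surface_faces_um2 = pm$surface_faces_um2,
               sav_um_inv = pm$sav_um_inv,
               status = if (i %in% open_ids) "open" else "closed",
               at_limit = pm$volume_um3 < detection_floor,
               x0 = bb[1], x1 = bb[2], y0 = bb[3], y1 = bb[4],
               z0 = zr[bb[5]], z1 = zr[bb[6]])
  })
  structure(do.call(rbind, rows), compartment_volume_um3 = comp_vol,
            voxel_size = voxel_size, roi_slices = zr,
            class = c("pore_table", "data.frame"))
}

#' Aggregate a pore table into a porosity report
#'
#' Cortical porosity is the total pore volume over the compartment
#' (envelope) volume; open and closed contributions always sum exactly to
#' the total. Closed-pore volume and SA:V means and SDs are reported for
#' pores above the detection floor.
#'
#' @param table A `pore_table` from [label_pores()].
#' @param compartment_volume Compartment volume in um^3 (defaults to the
#'   table's attribute).
#' @return A `porosity_report` list.
#' @export
porosity_report <- function(table,
                            compartment_volume = attr(table, "compartment_volume_um3")) {
  if (is.null(compartment_volume) || compartment_volume <= 0)
    stop("compartment volume must be positive")
  v_open <- sum(table$volume_um3[table$status == "open"])
  v_closed <- sum(table$volume_um3[table$status == "closed"])
  closed <- table[table$status == "closed" & !table$at_limit, , drop = FALSE]
  out <- list(compartment_volume_um3 = compartment_volume,
              total_pore_volume_um3 = v_open + v_closed,
              open_pore_volume_um3 = v_open,
              closed_pore_volume_um3 = v_closed,
              porosity = (v_open + v_closed) / compartment_volume,
              closed_porosity = v_closed / compartment_volume,
              n_pores = nrow(table),
              n_open = sum(table$status == "open"),
              n_closed = sum(table$status == "closed"),
              closed_volume_mean_um3 = if (nrow(closed)) mean(closed$volume_um3) else NA_real_,
              closed_volume_sd_um3 = if (nrow(closed) > 1) stats::sd(closed$volume_um3) else NA_real_,
              closed_sav_mean = if (nrow(closed)) mean(closed$sav_um_inv) else NA_real_,
              closed_sav_sd = if (nrow(closed) > 1) stats::sd(closed$sav_um_inv) else NA_real_)
  class(out) <- "porosity_report"
  out
}

#' @export
print.porosity_report <- function(x, ...) {
  cat(sprintf("<porosity_report> porosity %.3f%% (open %.3f%%, closed %.3f%%) | %d pores (%d open, %d closed)\n",
              100 * x$porosity, 100 * x$open_pore_volume_um3 / x$compartment_volume_um3,
              100 * x$closed_porosity, x$n_pores, x$n_open, x$n_closed))
  invisible(x)
}

#' One-call porosity measurement
#'
#' Convenience wrapper: global bone threshold, envelope, pore labelling
#' and aggregation.
#'
#' @param volume Density-valued [volume3d()].
#' @param roi Optional `roi_spec`.
#' @param min_density Bone threshold (default 0.238 g/cm^3 CaHA).
#' @param mesh Compute mesh surfaces per pore.
#' @return List `table` (pore_table) and `report` (porosity_report).
#' @export
measure_porosity <- function(volume, roi = NULL, min_density = 0.238, mesh = TRUE) {
  bm <- bone_mask(volume, min_density)
  tab <- label_pores(bm, roi = roi, voxel_size = volume$voxel_size, mesh = mesh)
  list(table = tab, report = porosity_report(tab))
}
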