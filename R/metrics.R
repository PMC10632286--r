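#' Segmentation agreement metrics
#'
#' Dice similarity coefficient, mean absolute surface distance, Hausdorff
#' distance and its 95th percentile, plus relative cartilage volume. Distances
#' can be computed mesh-based (per-vertex point-to-nearest-triangle) or
#' mask-based (boundary-voxel-center to boundary-voxel-center).
#'
#' @name segmentation-metrics
NULL

as_mask <- function(x, role = NULL) {
  if (inherits(x, "label_volume")) {
    if (is.null(role)) x$array != 0L else label_mask(x, role)
  } else if (is.logical(x) && length(dim(x)) == 3) {
    x
  } else stop("expected a label_volume or a 3D logical mask", call. = FALSE)
}

grid_of <- function(x) {
  if (inherits(x, "label_volume"))
    list(dim = dim(x$array), spacing = x$spacing, origin = x$origin)
  else list(dim = dim(x), spacing = 1, origin = c(0, 0, 0))
}

check_same_grid <- function(a, b) {
  ga <- grid_of(a); gb <- grid_of(b)
  if (!identical(ga$dim, gb$dim) || abs(ga$spacing - gb$spacing) > 1e-9 ||
      max(abs(ga$origin - gb$origin)) > 1e-9)
    stop("masks are on different grids (shape, spacing or origin differ)",
         call. = FALSE)
  ga
}

#' Dice similarity coefficient of two masks
#'
#' `2|A intersect B| / (|A| + |B|)` on voxel counts. Two empty masks agree
#' perfectly (1.0); one empty mask gives 0.
#'
#' @param a,b `label_volume`s or 3D logical masks on the same grid.
#' @param role optional label role when `label_volume`s carry several labels.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b, role = NULL) {
  check_same_grid(a, b)
  ma <- as_mask(a, role); mb <- as_mask(b, role)
  na <- sum(ma); nb <- sum(mb)
  if (na + nb == 0) return(1.0)
  2 * sum(ma & mb) / (na + nb)
}

# centers (mm) of foreground voxels that touch background via a 6-neighbour
# (or lie on the array border)
mask_boundary_points <- function(mask, spacing = 1, origin = c(0, 0, 0)) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb_all <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  idx <- which(core & !nb_all, arr.ind = TRUE)
  sweep((idx - 1) * spacing, 2, origin, `+`)
}

#' Directed surface-distance multisets between two shapes
#'
#' For meshes: the distance from every vertex of one mesh to the nearest
#' point on the other mesh's triangles (and vice versa). For masks: the
#' distance from every boundary voxel center to the nearest boundary voxel
#' center of the other mask.
#'
#' @param a,b two `surface_mesh`es, or two masks/`label_volume`s on the same
#'   grid.
#' @param role optional label role for `label_volume` inputs.
#' @return List with `ab` and `ba`, the two directed distance vectors (mm).
#' @export
surface_distances <- function(a, b, role = NULL) {
  if (inherits(a, "surface_mesh") && inherits(b, "surface_mesh")) {
    if (nrow(a$vertices) == 0 || nrow(b$vertices) == 0)
      stop("empty surface", call. = FALSE)
    ab <- cpp_point_surface(a$vertices, b$vertices, b$faces - 1L)$dist
    ba <- cpp_point_surface(b$vertices, a$vertices, a$faces - 1L)$dist
    return(list(ab = ab, ba = ba))
  }
  g <- check_same_grid(a, b)
  pa <- mask_boundary_points(as_mask(a, role), g$spacing, g$origin)
  pb <- mask_boundary_points(as_mask(b, role), g$spacing, g$origin)
  if (nrow(pa) == 0 || nrow(pb) == 0) stop("empty surface", call. = FALSE)
  list(ab = as.numeric(cpp_nn_dist(pa, pb)),
       ba = as.numeric(cpp_nn_dist(pb, pa)))
}

pooled_distances <- function(a, b, role = NULL) {
  d <- surface_distances(a, b, role)
  c(d$ab, d$ba)
}

#' Mean absolute surface distance
#'
#' Symmetric: the mean over the union of both directed distance multisets
#' (average symmetric surface distance).
#' @inheritParams surface_distances
#' @export
masd <- function(a, b, role = NULL) mean(pooled_distances(a, b, role))

#' Hausdorff distance (maximum over both directions)
#' @inheritParams surface_distances
#' @export
hausdorff <- function(a, b, role = NULL) max(pooled_distances(a, b, role))

#' 95th-percentile Hausdorff distance
#'
#' Linear interpolation between order statistics of the pooled multiset
#' (quantile type 7).
#' @inheritParams surface_distances
#' @export
hd95 <- function(a, b, role = NULL)
  as.numeric(stats::quantile(pooled_distances(a, b, role), 0.95, type = 7))

#' All four agreement metrics at once
#'
#' @inheritParams surface_distances
#' @return An `agreement_report`: list with `dsc`, `masd`, `hd`, `hd95`
#'   (mm except the dimensionless `dsc`) and `source` ("mesh" or "mask").
#'   For mesh inputs the Dice coefficient is computed on the meshes
#'   re-voxelized at `voxel` mm.
#' @param voxel re-voxelization edge for the mesh-based Dice path, mm.
#' @export
agreement_report <- function(a, b, role = NULL, voxel = 0.5) {
  meshes <- inherits(a, "surface_mesh") && inherits(b, "surface_mesh")
  d <- pooled_distances(a, b, role)
  dsc <- if (meshes) {
    va <- voxelize_mesh(a, voxel, pad = 2)
    vb <- voxelize_mesh(b, voxel, pad = 2, match_grid = va)
    dice(va, vb)
  } else dice(a, b, role)
  structure(list(dsc = dsc, masd = mean(d), hd = max(d),
                 hd95 = as.numeric(stats::quantile(d, 0.95, type = 7)),
                 source = if (meshes) "mesh" else "mask"),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report (%s)> DSC %.3f | MASD %.3f mm | HD %.2f mm | HD95 %.2f mm\n",
              x$source, x$dsc, x$masd, x$hd, x$hd95))
  invisible(x)
}

#' Voxelize a closed mesh onto a regular grid
#'
#' Fills voxels whose centers lie inside the mesh (ray parity along x).
#'
#' @param mesh a watertight `surface_mesh`.
#' @param spacing voxel edge, mm.
#' @param pad margin in voxels around the mesh bounding box.
#' @param match_grid optional `label_volume` whose grid should be reused (so
#'   two meshes can be compared voxel-wise).
#' @return A `label_volume` with a single label `inside = 1`.
#' @export
voxelize_mesh <- function(mesh, spacing = 0.5, pad = 2, match_grid = NULL) {
  if (is.null(match_grid)) {
    lo <- apply(mesh$vertices, 2, min) - pad * spacing
    hi <- apply(mesh$vertices, 2, max) + pad * spacing
    dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
    origin <- lo
  } else {
    dims <- dim(match_grid$array)
    origin <- match_grid$origin
    spacing <- match_grid$spacing
  }
  inside <- cpp_voxelize(mesh$vertices, mesh$faces - 1L, dims, spacing, origin)
  label_volume(array(as.integer(inside), dims), spacing, origin,
               label_map = c(inside = 1))
}

#' Relative cartilage volume
#'
#' Cartilage volume divided by bone volume, both from closed meshes. An
#' empty cartilage mesh (no faces) is allowed and gives RCV 0.
#'
#' @param bone_mesh,cartilage_mesh watertight `surface_mesh`es.
#' @param bone role tag recorded in the result.
#' @return A `cartilage_stats` list: `rcv`, `bone_volume`, `cartilage_volume`,
#'   `bone`.
#' @export
relative_cartilage_volume <- function(bone_mesh, cartilage_mesh,
                                      bone = bone_mesh$name) {
  bv <- mesh_volume(bone_mesh)
  cv <- if (nrow(cartilage_mesh$faces) == 0) 0 else mesh_volume(cartilage_mesh)
  structure(list(rcv = cv / bv, bone_volume = bv, cartilage_volume = cv,
                 bone = bone),
            class = "cartilage_stats")
}

#' @export
print.cartilage_stats <- function(x, ...) {
  cat(sprintf("<cartilage_stats '%s'> RCV %.4f (cartilage %.1f / bone %.1f mm^3)\n",
              x$bone, x$rcv, x$cartilage_volume, x$bone_volume))
  invisible(x)
}
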