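#' Triangulated surface meshes
#'
#' Bone and cartilage surfaces are closed triangle meshes with vertices in
#' physical millimetre coordinates. Faces are wound counter-clockwise when
#' seen from outside, so divergence-theorem volumes come out positive.
#'
#' @param vertices Nx3 numeric matrix, mm.
#' @param faces Mx3 integer matrix of 1-based vertex indices.
#' @param name role tag, e.g. "radius_deformed".
#' @param cut_faces optional integer vector of face rows created by plane
#'   cutting (cap faces); carried so the planning objective can address the
#'   osteotomy surfaces.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, name = "mesh", cut_faces = integer()) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces, name = name,
                 cut_faces = as.integer(cut_faces)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh '%s'> %d vertices, %d faces\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_corners <- function(mesh) {
  list(a = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       b = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       c = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

face_areas <- function(mesh) {
  fc <- face_corners(mesh)
  0.5 * sqrt(rowSums(cross3(fc$b - fc$a, fc$c - fc$a)^2))
}

#' Check that a mesh is closed (watertight) and consistently wound
#'
#' Every undirected edge must be used by exactly two faces, once in each
#' direction.
#' @param mesh a `surface_mesh`.
#' @return Logical; attribute `"why"` describes the first defect found.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(structure(FALSE, why = "empty mesh"))
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key))
    return(structure(FALSE, why = "duplicated directed edge (inconsistent winding or non-manifold)"))
  rkey <- paste(he[, 2], he[, 1])
  if (!all(rkey %in% key))
    return(structure(FALSE, why = "boundary edge present (mesh not closed)"))
  structure(TRUE, why = "")
}

#' Enclosed volume of a closed mesh
#'
#' Signed divergence-theorem volume (sum of signed tetrahedra against the
#' origin), returned positive for outward-wound meshes.
#'
#' @param mesh a watertight `surface_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  wt <- is_watertight(mesh)
  if (!wt)
    stop("mesh_volume needs a watertight mesh: ", attr(wt, "why"), call. = FALSE)
  fc <- face_corners(mesh)
  v <- sum(rowSums(fc$a * cross3(fc$b, fc$c))) / 6
  abs(v)
}

signed_mesh_volume <- function(mesh) {
  fc <- face_corners(mesh)
  sum(rowSums(fc$a * cross3(fc$b, fc$c))) / 6
}

#' Mirror a mesh across the sagittal (x = 0) plane
#'
#' Reflects vertices and reverses face winding, so an outward-wound mesh
#' stays outward-wound and its volume is unchanged. Used to turn the healthy
#' contralateral bone into a reconstruction template for the deformed side.
#'
#' @param mesh a `surface_mesh`.
#' @export
mirror_sagittal <- function(mesh) {
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  surface_mesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE],
               name = paste0(mesh$name, "_mirrored"),
               cut_faces = mesh$cut_faces)
}

#' Apply a rigid transform to a mesh
#' @param mesh a `surface_mesh`.
#' @param m a `rigid_transform`.
#' @export
transform_mesh <- function(mesh, m) {
  surface_mesh(transform_points(m, mesh$vertices), mesh$faces,
               name = mesh$name, cut_faces = mesh$cut_faces)
}

#' Principal (long) axis of an elongated mesh
#'
#' First principal direction of the vertex cloud, unit length, with its sign
#' chosen so the axis points from the proximal end toward the distal end.
#' Which end is proximal cannot be inferred from geometry alone; it is
#' declared by the caller (`proximal` = a point near the proximal end, or
#' `"+z"`/`"-z"` for the generator's convention that proximal is at low z).
#'
#' @param mesh a `surface_mesh`.
#' @param proximal either a length-3 point near the proximal end, or the
#'   string `"-z"` (default: proximal end at the low-z extreme, the
#'   generator's convention) or `"+z"`.
#' @return List with `axis` (unit 3-vector, proximal -> distal),
#'   `proximal_anchor` (mm point: extreme vertex projection at the proximal
#'   end), `centroid`, and `extent` (axial length, mm).
#' @export
principal_axis <- function(mesh, proximal = "-z") {
  v <- mesh$vertices
  if (nrow(v) < 3) stop("mesh too small for an axis", call. = FALSE)
  cen <- colMeans(v)
  vc <- sweep(v, 2, cen)
  sv <- svd(vc, nu = 0, nv = 3)
  if (sv$d[1] < 1e-9 || sv$d[1] / max(sv$d[2], 1e-300) < 1.05)
    stop("degenerate vertex cloud: no well-defined principal axis", call. = FALSE)
  axis <- sv$v[, 1]
  if (is.character(proximal)) {
    zdir <- if (identical(proximal, "-z")) 1 else -1
    if (abs(axis[3]) < 1e-12)
      stop("cannot orient axis from a z convention: axis is transverse", call. = FALSE)
    if (sign(axis[3]) != zdir) axis <- -axis
  } else {
    # axis should point away from the declared proximal point
    if (sum((cen - proximal) * axis) < 0) axis <- -axis
  }
  proj <- vc %*% axis
  list(axis = axis,
       proximal_anchor = cen + min(proj) * axis,
       centroid = cen,
       extent = max(proj) - min(proj))
}

#' Merge duplicate vertices and drop degenerate faces
#'
#' @param mesh a `surface_mesh`.
#' @param digits coordinates are rounded to this many digits to build the
#'   dedup key (geometry itself is not rounded).
#' @export
weld_vertices <- function(mesh, digits = 9) {
  key <- paste(round(mesh$vertices[, 1], digits),
               round(mesh$vertices[, 2], digits),
               round(mesh$vertices[, 3], digits))
  first <- !duplicated(key)
  map <- match(key, key[first])
  v <- mesh$vertices[first, , drop = FALSE]
  f <- matrix(map[mesh$faces], ncol = 3)
  good <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  cut <- intersect(mesh$cut_faces, which(good))
  # remap cut-face row numbers into the filtered face table
  newrow <- cumsum(good)
  surface_mesh(v, f[good, , drop = FALSE], name = mesh$name,
               cut_faces = newrow[cut])
}

#' Extract a surface mesh from one label of a volume
#'
#' The label's indicator function is iso-surfaced at 0.5 by marching
#' tetrahedra on the voxel grid (trilinear interpolation along cube edges),
#' yielding a watertight, outward-wound mesh in physical mm coordinates. If
#' the label occupies several 6-connected components, only the largest is
#' meshed, with a warning.
#'
#' @param vol a `label_volume`.
#' @param role label role name (e.g. "radius"), or an integer label value.
#' @return A `surface_mesh`.
#' @export
mesh_from_labels <- function(vol, role) {
  mask <- label_mask(vol, role)
  if (!any(mask)) stop("empty segmentation for role '", role, "'", call. = FALSE)
  cc <- cpp_largest_component(as.logical(mask), dim(mask))
  if (cc$n_components > 1) {
    warning("label '", role, "' has ", cc$n_components,
            " connected components; keeping the largest")
  }
  mask <- array(cc$mask, dim(mask))
  # pad with one background layer so the iso-surface closes at volume borders
  d <- dim(mask)
  field <- array(0, d + 2)
  field[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(mask)
  res <- cpp_march_tets(as.numeric(field), dim(field), 0.5, vol$spacing,
                        vol$origin - vol$spacing)
  weld_vertices(surface_mesh(res$vertices, res$faces, name = as.character(role)))
}
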