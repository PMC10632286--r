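#' Plane-parametrized virtual osteotomy and exhaustive plane search
#'
#' The cutting plane is parametrized by a station along the bone's
#' centerline (its center point lies on the centerline) and two tilts about
#' the transverse axes of the bone-local frame; rotation about the plane
#' normal itself is a no-op and is not searched. The plane cuts the deformed
#' bone into two fragments, the saved joint-end registrations reposition
#' them onto the mirrored contralateral template, and the objective measures
#' the residual gap between the two osteotomy surfaces.
#'
#' @name osteotomy-planning
NULL

#' Deterministic bone-local frame
#'
#' Orthonormal frame (e1, e2, e3) with e3 the proximal-to-distal long axis
#' and e1, e2 transverse, built deterministically from the principal axis.
#'
#' @param mesh a `surface_mesh`.
#' @param proximal proximal declaration, see [principal_axis()].
#' @return List with `e1`, `e2`, `e3` (unit vectors), `proximal_anchor`,
#'   `extent`.
#' @export
bone_frame <- function(mesh, proximal = "-z") {
  ax <- principal_axis(mesh, proximal = proximal)
  e3 <- ax$axis
  ref <- if (abs(e3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * e3) * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  list(e1 = e1, e2 = e2, e3 = e3,
       proximal_anchor = ax$proximal_anchor, extent = ax$extent)
}

# plane normal for tilts (ta about e1, tz about e2) away from the long axis
tilted_normal <- function(frame, tilt_a, tilt_z) {
  nf <- c(sin(tilt_z) * cos(tilt_a), -sin(tilt_a), cos(tilt_a) * cos(tilt_z))
  nf[1] * frame$e1 + nf[2] * frame$e2 + nf[3] * frame$e3
}

# recover (tilt_a, tilt_z) of a unit normal in a bone frame
normal_tilts <- function(frame, n) {
  nf <- c(sum(n * frame$e1), sum(n * frame$e2), sum(n * frame$e3))
  if (nf[3] < 0) nf <- -nf
  c(tilt_a = asin(max(-1, min(1, -nf[2]))), tilt_z = atan2(nf[1], nf[3]))
}

#' Osteotomy cutting plane
#'
#' @param p1p plane center point (mm), constrained to the bone centerline.
#' @param normal unit plane normal, pointing distal.
#' @param station axial distance of the center from the proximal end, mm.
#' @param tilt_a,tilt_z tilts (radians) about the bone frame's transverse
#'   axes e1 and e2.
#' @return An `osteotomy_plane`.
#' @export
osteotomy_plane <- function(p1p, normal, station = NA_real_,
                            tilt_a = NA_real_, tilt_z = NA_real_) {
  normal <- normal / sqrt(sum(normal^2))
  structure(list(p1p = as.numeric(p1p), normal = as.numeric(normal),
                 station = station, tilt_a = tilt_a, tilt_z = tilt_z),
            class = "osteotomy_plane")
}

#' @export
print.osteotomy_plane <- function(x, ...) {
  cat(sprintf("<osteotomy_plane> center (%.2f, %.2f, %.2f) mm, station %.1f mm, tilts (%.1f, %.1f) deg\n",
              x$p1p[1], x$p1p[2], x$p1p[3], x$station,
              x$tilt_a * 180 / pi, x$tilt_z * 180 / pi))
  invisible(x)
}

# ---- plane / mesh intersection ----

# Ordered loops of the intersection of a mesh with a plane, fully
# vectorized. Each crossing triangle contributes one segment whose endpoints
# lie on its two crossing edges; endpoints are computed once per undirected
# edge (with the edge's vertices in sorted order, so shared points are
# bit-identical) and segments are chained into closed loops through the
# node-degree-2 adjacency of a watertight mesh. Returns a list of ordered
# Nx3 point matrices.
plane_section_loops <- function(mesh, p0, n) {
  sd <- as.numeric(sweep(mesh$vertices, 2, p0) %*% n)
  sd[sd == 0] <- 1e-12
  f <- mesh$faces
  pos <- matrix(sd[f] > 0, ncol = 3)
  npos <- rowSums(pos)
  cr <- npos == 1L | npos == 2L
  if (!any(cr)) return(list())
  fx <- f[cr, , drop = FALSE]
  px <- pos[cr, , drop = FALSE]
  lone_mask <- px == (npos[cr] == 1L)  # TRUE at the lone vertex column
  lone <- max.col(lone_mask, ties.method = "first")
  idx <- cbind(seq_len(nrow(fx)), lone)
  a <- fx[idx]
  b <- fx[cbind(idx[, 1], lone %% 3L + 1L)]
  c <- fx[cbind(idx[, 1], (lone + 1L) %% 3L + 1L)]
  nv <- nrow(mesh$vertices) + 1
  ekey <- function(i, j) pmin(i, j) * nv + pmax(i, j)
  kab <- ekey(a, b); kac <- ekey(a, c)
  ue <- unique(c(kab, kac))
  ui <- floor(ue / nv); uj <- ue - ui * nv
  t <- sd[ui] / (sd[ui] - sd[uj])
  P <- mesh$vertices[ui, , drop = FALSE] +
    t * (mesh$vertices[uj, , drop = FALSE] - mesh$vertices[ui, , drop = FALSE])
  sa <- match(kab, ue); sb <- match(kac, ue)
  ns <- length(sa)
  # adjacency: every node of a closed section belongs to exactly 2 segments
  nodes <- c(sa, sb)
  segs <- rep(seq_len(ns), 2)
  ord <- order(nodes)
  so <- segs[ord]; no <- nodes[ord]
  first <- !duplicated(no)
  adj1 <- integer(length(ue)); adj2 <- integer(length(ue))
  adj1[no[first]] <- so[first]
  adj2[no[!first]] <- so[!first]
  other_end <- function(s, node) ifelse(sa[s] == node, sb[s], sa[s])
  used <- logical(ns)
  loops <- list()
  for (s0 in seq_len(ns)) {
    if (used[s0]) next
    used[s0] <- TRUE
    start <- sa[s0]
    path <- c(start, sb[s0])
    cur <- sb[s0]
    repeat {
      s1 <- adj1[cur]; s2 <- adj2[cur]
      nxt_seg <- if (s2 == 0L || used[s1] && !used[s2]) s2 else
                 if (!used[s1]) s1 else 0L
      if (nxt_seg == 0L) break
      used[nxt_seg] <- TRUE
      cur <- other_end(nxt_seg, cur)
      if (cur == start) break
      path <- c(path, cur)
    }
    if (length(path) >= 3)
      loops[[length(loops) + 1]] <- P[path, , drop = FALSE]
  }
  loops
}

# area centroid of a closed planar loop (3D points), via the shoelace
# formula in an in-plane basis
loop_centroid <- function(loop, n) {
  b1 <- loop[2, ] - loop[1, ]
  b1 <- b1 - sum(b1 * n) * n
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(n[2] * b1[3] - n[3] * b1[2],
          n[3] * b1[1] - n[1] * b1[3],
          n[1] * b1[2] - n[2] * b1[1])
  o <- loop[1, ]
  u <- as.numeric(sweep(loop, 2, o) %*% b1)
  v <- as.numeric(sweep(loop, 2, o) %*% b2)
  u2 <- c(u[-1], u[1]); v2 <- c(v[-1], v[1])
  crossp <- u * v2 - u2 * v
  area <- sum(crossp) / 2
  if (abs(area) < 1e-12) return(colMeans(loop))
  cu <- sum((u + u2) * crossp) / (6 * area)
  cv <- sum((v + v2) * crossp) / (6 * area)
  o + cu * b1 + cv * b2
}

#' Centerline of an elongated bone mesh
#'
#' Area centroids of the mesh's cross-sections at evenly spaced axial
#' stations, ordered proximal to distal.
#'
#' @param mesh a `surface_mesh` whose axial extent is at least 3x its
#'   transverse extent.
#' @param n_samples number of axial stations.
#' @param proximal proximal declaration, see [principal_axis()].
#' @return List with `points` (Kx3 mm), `stations` (axial mm from the
#'   proximal end), and the `frame` used.
#' @export
centerline <- function(mesh, n_samples = 50, proximal = "-z") {
  fr <- bone_frame(mesh, proximal = proximal)
  perp <- sweep(mesh$vertices, 2, fr$proximal_anchor)
  trans_extent <- 2 * max(sqrt(rowSums((perp %*% cbind(fr$e1, fr$e2))^2)))
  if (fr$extent < 3 * trans_extent)
    stop("mesh is not elongated (axial extent < 3x transverse extent)",
         call. = FALSE)
  stations <- seq(0.01, 0.99, length.out = n_samples) * fr$extent
  pts <- matrix(NA_real_, n_samples, 3)
  for (q in seq_len(n_samples)) {
    p0 <- fr$proximal_anchor + stations[q] * fr$e3
    loops <- plane_section_loops(mesh, p0, fr$e3)
    if (length(loops) == 0) next
    areas <- vapply(loops, function(L) nrow(L), numeric(1))
    pts[q, ] <- loop_centroid(loops[[which.max(areas)]], fr$e3)
  }
  ok <- !is.na(pts[, 1])
  if (mean(ok) < 0.8)
    stop("more than 20% of centerline stations have empty cross-sections",
         call. = FALSE)
  list(points = pts[ok, , drop = FALSE], stations = stations[ok], frame = fr)
}

#' Cut a closed mesh with an osteotomy plane
#'
#' Faces crossing the plane are split exactly; the planar openings are
#' capped by fan triangulation of each intersection loop (cross-sections are
#' assumed star-shaped, which holds for long-bone shafts). Cap faces are
#' tagged in `cut_faces` so the planning objective can address the osteotomy
#' surfaces. The proximal fragment collects everything on the negative side
#' of the plane normal.
#'
#' @param mesh a watertight `surface_mesh`.
#' @param plane an `osteotomy_plane` with the normal pointing distal.
#' @return List with `proximal` and `distal` `surface_mesh`es.
#' @export
cut_with_plane <- function(mesh, plane) {
  p0 <- plane$p1p; n <- plane$normal
  sd <- as.numeric(sweep(mesh$vertices, 2, p0) %*% n)
  sd[sd == 0] <- 1e-12
  if (all(sd > 0) || all(sd < 0))
    stop("plane does not intersect the mesh interior", call. = FALSE)
  f <- mesh$faces
  side <- matrix(sd[f] > 0, ncol = 3)
  npos <- rowSums(side)

  verts <- mesh$vertices
  new_idx <- new.env(parent = emptyenv())
  edge_pt_idx <- function(i, j) {
    if (i > j) { tmp <- i; i <- j; j <- tmp }  # sorted: bit-identical with
    key <- paste0(i, "_", j)                   # plane_section_loops points
    id <- new_idx[[key]]
    if (is.null(id)) {
      t <- sd[i] / (sd[i] - sd[j])
      p <- mesh$vertices[i, ] + t * (mesh$vertices[j, ] - mesh$vertices[i, ])
      verts <<- rbind(verts, p)
      id <- nrow(verts)
      new_idx[[key]] <- id
    }
    id
  }

  prox_faces <- f[npos == 0, , drop = FALSE]
  dist_faces <- f[npos == 3, , drop = FALSE]
  cross_rows <- which(npos == 1 | npos == 2)
  for (q in cross_rows) {
    tri <- f[q, ]; s <- side[q, ]
    lone_pos <- sum(s) == 1
    lone <- if (lone_pos) which(s) else which(!s)
    # rotate so the lone vertex comes first, preserving winding
    ord <- switch(lone, 1:3, c(2, 3, 1), c(3, 1, 2))
    a <- tri[ord[1]]; b <- tri[ord[2]]; c <- tri[ord[3]]
    pab <- edge_pt_idx(a, b)
    pac <- edge_pt_idx(a, c)
    lone_tri <- rbind(c(a, pab, pac))
    quad_tris <- rbind(c(pab, b, c), c(pab, c, pac))
    if (lone_pos) {
      dist_faces <- rbind(dist_faces, lone_tri)
      prox_faces <- rbind(prox_faces, quad_tris)
    } else {
      prox_faces <- rbind(prox_faces, lone_tri)
      dist_faces <- rbind(dist_faces, quad_tris)
    }
  }

  loops <- plane_section_loops(mesh, p0, n)
  if (length(loops) == 0)
    stop("plane does not intersect the mesh interior", call. = FALSE)

  cap_fan <- function(loop, want_normal) {
    # match loop points back to the split vertices by coordinates
    key <- function(m) paste(round(m[, 1], 9), round(m[, 2], 9), round(m[, 3], 9))
    idx <- match(key(loop), key(verts))
    if (anyNA(idx)) stop("internal: cap loop vertex not found", call. = FALSE)
    # orient the loop counter-clockwise around want_normal
    cen <- colMeans(loop)
    r1 <- loop[1, ] - cen
    r2 <- loop[2, ] - cen
    cr <- c(r1[2] * r2[3] - r1[3] * r2[2],
            r1[3] * r2[1] - r1[1] * r2[3],
            r1[1] * r2[2] - r1[2] * r2[1])
    if (sum(cr * want_normal) < 0) idx <- rev(idx)
    k <- length(idx)
    cbind(rep(idx[1], k - 2), idx[2:(k - 1)], idx[3:k])
  }
  prox_caps <- do.call(rbind, lapply(loops, cap_fan, want_normal = n))
  dist_caps <- do.call(rbind, lapply(loops, cap_fan, want_normal = -n))

  prox_cut <- nrow(prox_faces) + seq_len(nrow(prox_caps))
  dist_cut <- nrow(dist_faces) + seq_len(nrow(dist_caps))
  prox <- weld_vertices(surface_mesh(verts, rbind(prox_faces, prox_caps),
                                     name = paste0(mesh$name, "_prox"),
                                     cut_faces = prox_cut))
  dist <- weld_vertices(surface_mesh(verts, rbind(dist_faces, dist_caps),
                                     name = paste0(mesh$name, "_dist"),
                                     cut_faces = dist_cut))
  list(proximal = prox, distal = dist)
}

#' Reposition osteotomy fragments with the saved registrations
#'
#' @param proximal,distal `surface_mesh` fragments from [cut_with_plane()].
#' @param m_prox,m_dist `rigid_transform`s from [register_joint_ends()].
#' @return List with the two transformed fragments.
#' @export
reconstruct <- function(proximal, distal, m_prox, m_dist) {
  list(proximal = transform_mesh(proximal, m_prox),
       distal = transform_mesh(distal, m_dist))
}

cut_face_vertices <- function(mesh) {
  if (length(mesh$cut_faces) == 0)
    stop("mesh carries no cut-face tags (was it produced by cut_with_plane?)",
         call. = FALSE)
  idx <- unique(as.vector(mesh$faces[mesh$cut_faces, , drop = FALSE]))
  mesh$vertices[idx, , drop = FALSE]
}

symmetric_set_gap <- function(A, B) {
  mean(c(as.numeric(cpp_nn_dist(A, B)), as.numeric(cpp_nn_dist(B, A))))
}

#' Planning objective for a reconstructed fragment pair
#'
#' The primary term is the symmetric mean distance (mm) between the two
#' osteotomy (cut-face) vertex sets after reconstruction: zero when the
#' fragments mate exactly. Optionally, a volume-overlap reward with the
#' contralateral template is subtracted:
#' `gap - overlap_weight * (overlap volume / contralateral volume) * 1 mm`.
#' The default weight of 0 reproduces pure gap minimization.
#'
#' @param recon_prox,recon_dist reconstructed fragments with cut-face tags.
#' @param contralateral mirrored contralateral `surface_mesh` (only needed
#'   when `overlap_weight > 0`).
#' @param overlap_weight dimensionless weight of the overlap term.
#' @param overlap_voxel voxel edge for the overlap computation, mm.
#' @return Objective value, mm.
#' @export
plan_objective <- function(recon_prox, recon_dist, contralateral = NULL,
                           overlap_weight = 0, overlap_voxel = 1) {
  gap <- symmetric_set_gap(cut_face_vertices(recon_prox),
                           cut_face_vertices(recon_dist))
  if (overlap_weight > 0) {
    if (is.null(contralateral))
      stop("overlap term requires the contralateral mesh", call. = FALSE)
    ref <- voxelize_mesh(contralateral, overlap_voxel, pad = 2)
    vp <- voxelize_mesh(recon_prox, match_grid = ref)
    vd <- voxelize_mesh(recon_dist, match_grid = ref)
    uni <- (vp$array == 1L) | (vd$array == 1L)
    overlap <- sum(uni & (ref$array == 1L)) / sum(ref$array == 1L)
    gap <- gap - overlap_weight * overlap * 1
  }
  gap
}

#' Search grid specification for the exhaustive plane search
#'
#' @param station_step spacing of centerline stations, mm.
#' @param station_band fraction band of the axial extent searched (the
#'   registered joint ends are excluded).
#' @param tilt_max largest tilt magnitude about each transverse axis, rad.
#' @param tilt_step tilt increment, rad.
#' @return A `search_grid` list.
#' @export
search_grid <- function(station_step = 2, station_band = c(0.2, 0.8),
                        tilt_max = 45 * pi / 180, tilt_step = 5 * pi / 180) {
  structure(list(station_step = station_step, station_band = station_band,
                 tilt_max = tilt_max, tilt_step = tilt_step),
            class = "search_grid")
}

# all (station, tilt_a, tilt_z) nodes of a grid for a given axial extent
grid_nodes <- function(grid, extent) {
  stations <- seq(grid$station_band[1] * extent, grid$station_band[2] * extent,
                  by = grid$station_step)
  tilts <- seq(-grid$tilt_max, grid$tilt_max, by = grid$tilt_step)
  expand.grid(station = stations, tilt_a = tilts, tilt_z = tilts,
              KEEP.OUT.ATTRS = FALSE)
}

# centerline point (cross-section area centroid) at one axial station
station_centroid <- function(mesh, frame, station) {
  p_axis <- frame$proximal_anchor + station * frame$e3
  loops <- plane_section_loops(mesh, p_axis, frame$e3)
  if (length(loops) == 0) return(NULL)
  sizes <- vapply(loops, nrow, numeric(1))
  loop_centroid(loops[[which.max(sizes)]], frame$e3)
}

# plane at one grid node; p1p is the cross-section centroid at the station
node_plane <- function(mesh, frame, station, tilt_a, tilt_z, p1p = NULL) {
  if (is.null(p1p)) p1p <- station_centroid(mesh, frame, station)
  if (is.null(p1p)) return(NULL)
  osteotomy_plane(p1p, tilted_normal(frame, tilt_a, tilt_z),
                  station = station, tilt_a = tilt_a, tilt_z = tilt_z)
}

# light-weight objective at one node: the cut polygon (plane/mesh section)
# is the shared boundary of both future cut faces; transform it by each
# fragment matrix and measure the symmetric gap. Identical vertex sets to
# the capped-fragment objective, because caps add no interior vertices.
node_objective <- function(mesh, plane, m_prox, m_dist) {
  loops <- plane_section_loops(mesh, plane$p1p, plane$normal)
  if (length(loops) == 0) return(NA_real_)
  pts <- do.call(rbind, loops)
  symmetric_set_gap(transform_points(m_prox, pts), transform_points(m_dist, pts))
}

#' Exhaustive search for the optimal osteotomy plane
#'
#' Evaluates the planning objective at every node of the search grid
#' (centerline stations x transverse tilt pairs) and returns the global
#' minimum. Ties are broken deterministically: smallest distance of the
#' station from mid-shaft, then lexicographically by (station, tilt_a,
#' tilt_z).
#'
#' @param deformed deformed bone `surface_mesh`, pre-aligned to the
#'   contralateral frame.
#' @param contralateral_mirrored the mirrored contralateral `surface_mesh`.
#' @param m_prox,m_dist joint-end registrations from [register_joint_ends()].
#' @param grid a [search_grid()].
#' @param overlap_weight objective overlap weight (see [plan_objective()]).
#' @param proximal proximal declaration, see [principal_axis()].
#' @return A `planning_result` with the optimal plane, the reconstructed
#'   fragments, the realignment transform, the objective value, the wedge
#'   type and the secondary-cut fields, plus the evaluated grid table.
#' @export
exhaustive_search <- function(deformed, contralateral_mirrored, m_prox, m_dist,
                              grid = search_grid(), overlap_weight = 0,
                              proximal = "-z") {
  frame <- bone_frame(deformed, proximal = proximal)
  nodes <- grid_nodes(grid, frame$extent)
  if (nrow(nodes) == 0) stop("empty search grid", call. = FALSE)
  vals <- rep(NA_real_, nrow(nodes))
  planes <- vector("list", nrow(nodes))
  stations <- unique(nodes$station)
  centroids <- lapply(stations, function(s)
    station_centroid(deformed, frame, s))
  names(centroids) <- as.character(stations)
  for (q in seq_len(nrow(nodes))) {
    p1p <- centroids[[as.character(nodes$station[q])]]
    if (is.null(p1p)) next
    pl <- node_plane(deformed, frame, nodes$station[q], nodes$tilt_a[q],
                     nodes$tilt_z[q], p1p = p1p)
    planes[[q]] <- pl
    vals[q] <- node_objective(deformed, pl, m_prox, m_dist)
  }
  if (all(is.na(vals)))
    stop("no grid plane intersects the bone", call. = FALSE)
  mid <- frame$extent / 2
  ord <- order(vals, abs(nodes$station - mid), nodes$station, nodes$tilt_a,
               nodes$tilt_z, na.last = TRUE)
  best <- ord[1]
  plane <- planes[[best]]
  frags <- cut_with_plane(deformed, plane)
  recon <- reconstruct(frags$proximal, frags$distal, m_prox, m_dist)
  realign <- relative(m_prox, m_dist)
  res <- structure(list(
    plane = plane, secondary_plane = NULL,
    proximal_fragment = recon$proximal, distal_fragment = recon$distal,
    m_prox = as_rigid(m_prox), m_dist = as_rigid(m_dist),
    realignment = realign,
    objective = vals[best], overlap_weight = overlap_weight,
    wedge_type = NA_character_, secondary_intersects_primary = NA,
    frame = frame, grid = grid,
    grid_table = cbind(nodes, objective = vals)
  ), class = "planning_result")
  if (overlap_weight > 0)
    res$objective <- plan_objective(recon$proximal, recon$distal,
                                    contralateral_mirrored, overlap_weight)
  secondary_cut(res)
}

#' @export
print.planning_result <- function(x, ...) {
  cat(sprintf("<planning_result> station %.1f mm, tilts (%.1f, %.1f) deg, objective %.4f mm\n",
              x$plane$station, x$plane$tilt_a * 180 / pi,
              x$plane$tilt_z * 180 / pi, x$objective))
  cat(sprintf("  wedge type: %s%s\n", x$wedge_type,
              if (isTRUE(!is.na(x$secondary_intersects_primary)))
                sprintf(" (secondary cut %s primary)",
                        if (isTRUE(x$secondary_intersects_primary)) "intersects"
                        else "clear of") else ""))
  invisible(x)
}

#' Derive the secondary cut of a closing wedge
#'
#' If the reconstructed fragments interpenetrate, the osteotomy is a closing
#' wedge and a secondary cut is required: the image of the primary plane
#' under the realignment transform (the distal fragment's mated face). The
#' red/green flag records whether the secondary plane crosses the primary
#' cut polygon inside the bone.
#'
#' @param result a `planning_result`.
#' @param tol interpenetration tolerance, mm.
#' @return The `planning_result` with `wedge_type`, `secondary_plane`, and
#'   `secondary_intersects_primary` filled in.
#' @export
secondary_cut <- function(result, tol = 1e-6) {
  plane <- result$plane
  # the shared cut polygon, back in the deformed bone's frame
  poly <- transform_points(invert(result$m_prox),
                           cut_face_vertices(result$proximal_fragment))
  # pose of the two cut faces after reconstruction, in the template frame
  Rp <- result$m_prox$matrix[1:3, 1:3]
  n_prox <- as.numeric(Rp %*% plane$normal)
  p_prox <- transform_points(result$m_prox, matrix(plane$p1p, 1))[1, ]
  dist_pts <- transform_points(result$m_dist, poly)
  s <- as.numeric(sweep(dist_pts, 2, p_prox) %*% n_prox)
  if (min(s) < -tol) {
    result$wedge_type <- "closing"
    M <- result$realignment
    sec_n <- as.numeric(M$matrix[1:3, 1:3] %*% plane$normal)
    sec_p <- transform_points(M, matrix(plane$p1p, 1))[1, ]
    result$secondary_plane <- osteotomy_plane(sec_p, sec_n)
    # red if the primary polygon straddles the secondary plane
    ss <- as.numeric(sweep(poly, 2, sec_p) %*% sec_n)
    result$secondary_intersects_primary <- min(ss) < -tol && max(ss) > tol
  } else {
    result$wedge_type <- "opening"
    result$secondary_plane <- NULL
    result$secondary_intersects_primary <- NA
  }
  result
}

#' Compare two planned osteotomy planes
#'
#' Axial location difference and tilt differences in a shared bone frame.
#' `delta_z` is the signed axial offset of plane b relative to plane a,
#' positive toward distal; `psi_a` and `psi_z` are the differences of the
#' plane tilts about the frame's two transverse axes.
#'
#' @param a,b `planning_result`s for the same bone.
#' @param frame optional shared `bone_frame`; defaults to a's frame.
#' @return List with `delta_z` (mm), `psi_a`, `psi_z` (radians).
#' @export
compare_planes <- function(a, b, frame = a$frame) {
  station <- function(r)
    sum((r$plane$p1p - frame$proximal_anchor) * frame$e3)
  ta <- normal_tilts(frame, a$plane$normal)
  tb <- normal_tilts(frame, b$plane$normal)
  list(delta_z = station(b) - station(a),
       psi_a = tb[["tilt_a"]] - ta[["tilt_a"]],
       psi_z = tb[["tilt_z"]] - ta[["tilt_z"]])
}
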