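#' Joint-end registration against the mirrored contralateral bone
#'
#' The deformed bone is compared to the mirrored healthy contralateral bone
#' in three steps: a deterministic initial alignment of the whole bones, the
#' isolation of proximal and distal joint-end fragments, and a rigid
#' point-to-surface ICP registration of each fragment to its counterpart.
#' The two resulting matrices M_prox and M_dist define the realignment
#' M = M_prox^-1 x M_dist.
#'
#' @name registration
NULL

# faces subset -> standalone mesh with renumbered vertices
submesh <- function(mesh, face_rows, name = mesh$name) {
  f <- mesh$faces[face_rows, , drop = FALSE]
  keep <- sort(unique(as.vector(f)))
  map <- integer(nrow(mesh$vertices))
  map[keep] <- seq_along(keep)
  surface_mesh(mesh$vertices[keep, , drop = FALSE],
               matrix(map[f], ncol = 3), name = name)
}

# deterministic subsample of rows (every k-th) for candidate scoring
thin_rows <- function(m, n_target) {
  if (nrow(m) <= n_target) return(m)
  m[unique(round(seq(1, nrow(m), length.out = n_target))), , drop = FALSE]
}

rms_to_surface <- function(pts, fixed) {
  d <- cpp_point_surface(pts, fixed$vertices, fixed$faces - 1L)$dist
  sqrt(mean(d^2))
}

#' Deterministic initial alignment of two bone meshes
#'
#' Centroid translation plus principal-axes rotation. The principal axes
#' leave four proper-rotation sign ambiguities; all four candidates are
#' scored by RMS distance to the fixed surface and the best is refined by a
#' short whole-bone ICP. Fully deterministic for fixed inputs.
#'
#' @param moving,fixed `surface_mesh`es.
#' @param refine_iter ICP refinement iterations.
#' @return A `rigid_transform` mapping `moving` into the frame of `fixed`.
#'   When a strongly different pose (rotation > 60 degrees from the winner)
#'   fits almost as well — which happens when a deformity masks a flip —
#'   it is attached as attribute `"runner_up"` so callers can arbitrate on
#'   downstream evidence (see [register_joint_ends()]).
#' @export
initial_align <- function(moving, fixed, refine_iter = 30) {
  cm <- colMeans(moving$vertices)
  cf <- colMeans(fixed$vertices)
  sm <- svd(sweep(moving$vertices, 2, cm), nu = 0, nv = 3)
  sf <- svd(sweep(fixed$vertices, 2, cf), nu = 0, nv = 3)
  if (sm$d[2] < 1e-9 || sf$d[2] < 1e-9)
    stop("degenerate principal axes: vertex cloud has no spread in >= 2 dimensions",
         call. = FALSE)
  Vm <- sm$v; Vf <- sf$v
  if (det(Vm) < 0) Vm[, 3] <- -Vm[, 3]
  if (det(Vf) < 0) Vf[, 3] <- -Vf[, 3]
  # The principal-axes rotation leaves sign flips (end swap, 180-degree
  # turns) and, for near-tubular bones, azimuthal ambiguities; a mid-shaft
  # deformity can also bias any whole-bone score. So: 4 proper sign
  # combinations x a coarse fan of azimuthal rotations about the long axis,
  # each polished by a short ICP on probe points drawn from the two joint
  # ends (which the deformity does not touch), judged on the converged
  # end-region residual. Deterministic throughout.
  # Candidate fan: 4 proper sign combinations of the principal axes x 8
  # azimuthal rotations about the fixed bone's long axis. The transverse
  # principal directions of a near-tubular cloud are noise-arbitrary, so
  # azimuth must be searched, not inferred. Candidates are polished by a
  # short ICP on a deterministic whole-bone probe subsample and judged on
  # the converged residual: flips and spun poses cannot fit curvature and
  # end shape over the full length, while probes restricted to sub-regions
  # can drape spuriously. Deterministic throughout.
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  azimuths <- seq(0, 2 * pi, by = pi / 4)[-9]
  probe <- thin_rows(moving$vertices, 500)
  cands <- list()
  rmss <- numeric(0)
  for (s in signs) {
    R0 <- Vf %*% diag(s) %*% t(Vm)
    for (g in azimuths) {
      R <- rot_axis_angle(Vf[, 1], g) %*% R0
      cand <- rigid_from_rt(R, cf - R %*% cm)
      pm <- surface_mesh(transform_points(cand, probe), matrix(integer(0), 0, 3))
      out <- icp_register(pm, fixed, max_iter = 12)
      cands[[length(cands) + 1]] <- compose(out$transform, cand)
      rmss <- c(rmss, out$rms_residual)
    }
  }
  ord <- order(rmss)
  best <- cands[[ord[1]]]
  # A deformity can make a flipped whole-bone pose fit almost as well as
  # the true one; keep the best pose that differs by a large rotation as a
  # runner-up so the caller can arbitrate on fragment-level residuals.
  geo <- function(a, b) {
    R <- crossprod(a$matrix[1:3, 1:3], b$matrix[1:3, 1:3])
    acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  }
  # up to two runners, each > 60 degrees from every already-kept pose
  kept <- list(best)
  runners <- list()
  for (q in ord[-1]) {
    if (length(runners) >= 2) break
    far <- all(vapply(kept, function(k) geo(k, cands[[q]]) > pi / 3, logical(1)))
    if (far) {
      runners <- c(runners, list(cands[[q]]))
      kept <- c(kept, list(cands[[q]]))
    }
  }
  refine <- function(pose) {
    # refine on a deterministic vertex subsample; correspondences still go
    # to the full fixed surface
    thin <- surface_mesh(thin_rows(transform_points(pose, moving$vertices), 1500),
                         matrix(integer(0), 0, 3), name = moving$name)
    out <- icp_register(thin, fixed, max_iter = refine_iter)
    compose(out$transform, pose)
  }
  if (refine_iter > 0) {
    best <- refine(best)
    runners <- lapply(runners, refine)
  }
  attr(best, "runner_up") <- if (length(runners) > 0) runners else NULL
  best
}

#' Isolate a proximal or distal joint-end fragment
#'
#' Keeps the faces whose centroids project onto the bone's principal axis
#' within the terminal `fraction` of the axial extent measured from the
#' chosen end.
#'
#' @param mesh a `surface_mesh` of a whole bone.
#' @param end `"proximal"` or `"distal"`.
#' @param fraction fraction of the axial extent to keep, in (0, 0.5].
#' @param proximal proximal-end declaration passed to [principal_axis()].
#' @param min_vertices smallest acceptable fragment.
#' @return A `joint_fragment`: list with `mesh`, `end`, `source_bone`,
#'   `extent_fraction`.
#' @export
isolate_end_fragment <- function(mesh, end = c("proximal", "distal"),
                                 fraction = 0.2, proximal = "-z",
                                 min_vertices = 50) {
  end <- match.arg(end)
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 0.5)
    stop("fraction must lie in (0, 0.5]", call. = FALSE)
  ax <- principal_axis(mesh, proximal = proximal)
  cen <- (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
          mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
          mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
  s <- as.numeric(sweep(cen, 2, ax$proximal_anchor) %*% ax$axis)
  keep <- if (end == "proximal") s <= fraction * ax$extent
          else s >= (1 - fraction) * ax$extent
  if (!any(keep)) stop("no faces in the requested end band", call. = FALSE)
  frag <- submesh(mesh, which(keep), name = paste(mesh$name, end, sep = "_"))
  if (nrow(frag$vertices) < min_vertices)
    stop("fragment has only ", nrow(frag$vertices),
         " vertices; increase `fraction`", call. = FALSE)
  structure(list(mesh = frag, end = end, source_bone = mesh$name,
                 extent_fraction = fraction),
            class = "joint_fragment")
}

#' @export
print.joint_fragment <- function(x, ...) {
  cat(sprintf("<joint_fragment %s of '%s'> %d vertices (fraction %.2f)\n",
              x$end, x$source_bone, nrow(x$mesh$vertices), x$extent_fraction))
  invisible(x)
}

#' Rigid point-to-surface ICP registration
#'
#' Every vertex of the moving surface is matched to its nearest point on the
#' fixed surface. Each iteration applies a closed-form rigid update:
#' a linearized point-to-plane solve (fast convergence near the optimum),
#' falling back to the Kabsch point-to-point solution whenever the
#' point-to-plane step would not decrease the RMS residual — so the residual
#' is non-increasing by construction. Correspondences farther than
#' `gate_factor` times the current RMS are dropped (after the first
#' iteration). All vertices are used — no random sampling — so the result is
#' deterministic.
#'
#' @param moving a `joint_fragment` or `surface_mesh`.
#' @param fixed a `surface_mesh`.
#' @param max_iter iteration cap (>= 1).
#' @param tol convergence threshold on the RMS change, mm.
#' @param gate_factor correspondence gate, multiples of the current RMS.
#' @param fail_distance if the initial median correspondence distance
#'   exceeds this (mm), registration is considered impossible.
#' @return A `registration_outcome`: `transform` (maps moving into the fixed
#'   frame), `rms_residual` (mm), `iterations`, `converged`, `rms_history`.
#' @export
icp_register <- function(moving, fixed, max_iter = 100, tol = 1e-4,
                         gate_factor = 10, fail_distance = 200) {
  if (inherits(moving, "joint_fragment")) moving <- moving$mesh
  if (!is.numeric(max_iter) || max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (!is.numeric(tol) || tol <= 0) stop("tol must be > 0", call. = FALSE)
  pts0 <- moving$vertices
  total <- rigid_transform()
  pts <- pts0
  rms_prev <- Inf
  rms_hist <- numeric(0)
  converged <- FALSE
  iters <- 0
  ffaces <- fixed$faces - 1L
  fnorm <- face_unit_normals(fixed)
  surf_rms <- function(p) {
    sqrt(mean(cpp_point_surface(p, fixed$vertices, ffaces)$dist^2))
  }
  for (it in seq_len(max_iter)) {
    iters <- it
    corr <- cpp_point_surface(pts, fixed$vertices, ffaces)
    d <- corr$dist
    if (it == 1 && stats::median(d) > fail_distance)
      stop("registration failure: surfaces are more than ", fail_distance,
           " mm apart", call. = FALSE)
    rms <- sqrt(mean(d^2))
    rms_hist <- c(rms_hist, rms)
    keep <- if (it == 1 || rms == 0) rep(TRUE, length(d))
            else d <= gate_factor * rms
    if (!any(keep))
      stop("registration failure: no correspondences within the gate", call. = FALSE)
    if (abs(rms_prev - rms) < tol) { converged <- TRUE; break }
    rms_prev <- rms
    P <- pts[keep, , drop = FALSE]
    Q <- corr$nearest[keep, , drop = FALSE]
    upd <- point_to_plane_update(P, Q, fnorm[corr$tri[keep], , drop = FALSE])
    accept <- FALSE
    if (!is.null(upd)) {
      cand <- compose(upd, total)
      cand_pts <- transform_points(cand, pts0)
      if (surf_rms(cand_pts) <= rms) {
        total <- cand; pts <- cand_pts; accept <- TRUE
      }
    }
    if (!accept) {
      total <- compose(kabsch(P, Q), total)
      pts <- transform_points(total, pts0)
    }
  }
  structure(list(transform = total, rms_residual = rms_hist[length(rms_hist)],
                 iterations = iters, converged = converged,
                 rms_history = rms_hist),
            class = "registration_outcome")
}

#' @export
print.registration_outcome <- function(x, ...) {
  cat(sprintf("<registration_outcome> rms %.4g mm after %d iterations (%s)\n",
              x$rms_residual, x$iterations,
              if (x$converged) "converged" else "iteration cap"))
  invisible(x)
}

face_unit_normals <- function(mesh) {
  fc <- face_corners(mesh)
  n <- cross3(fc$b - fc$a, fc$c - fc$a)
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

# linearized point-to-plane rigid update: minimizes sum over i of
# ((p_i + w x p_i + t - q_i) . n_i)^2 for small rotation w; NULL when the
# normal equations are singular
point_to_plane_update <- function(P, Q, N) {
  cxn <- cross3(P, N)
  A <- cbind(cxn, N)
  b <- -rowSums((P - Q) * N)
  sol <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                  error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  w <- sol[1:3]
  t <- sol[4:6]
  ang <- sqrt(sum(w^2))
  R <- if (ang < 1e-300) diag(3) else rot_axis_angle(w / ang, ang)
  rigid_from_rt(R, t)
}

# closed-form least-squares rigid transform taking P onto Q (row-paired)
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_from_rt(R, cq - R %*% cp)
}

#' Register both joint ends of a deformed bone to the mirrored contralateral
#'
#' Isolates the proximal and distal fragments of the (pre-aligned) deformed
#' bone and registers each to the corresponding end region of the mirrored
#' contralateral bone, returning the two matrices whose difference is the
#' realignment.
#'
#' @param deformed,contralateral_mirrored pre-aligned `surface_mesh`es (see
#'   [initial_align()]).
#' @param fraction fragment extent fraction of the axial length.
#' @param proximal proximal-end declaration (see [principal_axis()]).
#' @param max_correction optional trust region, radians: when the caller
#'   vouches for the pre-alignment, fan outcomes rotated further than this
#'   from the start are discarded (the legitimate per-end correction is
#'   bounded by the deformity), which stops boundary noise from capturing
#'   a spun pose on landmark-poor ends. NULL (default) = unrestricted.
#' @param end_starts optional list with `prox` and `dist`
#'   `rigid_transform`s used as per-end starting registrations (e.g. the
#'   registrations of another segmentation variant of the same bone). The
#'   azimuthal fan then shrinks to a small local one around each start and
#'   the trust region is measured relative to it.
#' @param ... passed to [icp_register()].
#' @return List with `m_prox`, `m_dist` (`rigid_transform`s), and the two
#'   `registration_outcome`s (`prox_outcome`, `dist_outcome`).
#' @export
register_joint_ends <- function(deformed, contralateral_mirrored,
                                fraction = 0.2, proximal = "-z",
                                max_correction = NULL, end_starts = NULL, ...) {
  fixed_fraction <- min(0.5, fraction * 1.5)
  res <- lapply(c("proximal", "distal"), function(end) {
    frag <- isolate_end_fragment(deformed, end, fraction, proximal = proximal)
    target <- isolate_end_fragment(contralateral_mirrored, end, fixed_fraction,
                                   proximal = proximal)
    # multi-start over a fan of azimuthal rotations about the target's
    # long axis: near-tubular fragments breed azimuthal local minima that
    # plain ICP cannot cross. The fan is full circle by default; when the
    # caller supplies a per-end starting registration the fan shrinks to
    # a small local one around it. With `max_correction` set, outcomes
    # beyond the trust region are discarded when any in-bound one exists.
    ax <- principal_axis(target$mesh, proximal = proximal)
    probe <- thin_rows(frag$mesh$vertices, 600)
    ffix <- target$mesh
    base <- rigid_transform()
    starts <- seq(0, 2 * pi, by = pi / 4)[-9]
    trust <- max_correction
    if (!is.null(end_starts)) {
      base <- as_rigid(end_starts[[if (end == "proximal") "prox" else "dist"]])
      starts <- seq(-pi / 8, pi / 8, by = pi / 8)
      if (is.null(trust)) trust <- 30 * pi / 180
    }
    probe_b <- transform_points(base, probe)
    cen <- colMeans(probe_b)
    outs <- list()
    for (g in starts) {
      R <- rot_axis_angle(ax$axis, g)
      cand <- compose(
        compose(rigid_from_rt(diag(3), cen),
                compose(rigid_from_rt(R), rigid_from_rt(diag(3), -cen))),
        base)
      pm <- surface_mesh(transform_points(cand, probe), matrix(integer(0), 0, 3))
      out <- tryCatch(icp_register(pm, ffix, max_iter = 15),
                      error = function(e) NULL)
      if (is.null(out)) next
      pose <- compose(out$transform, cand)
      Rrel <- compose(pose, invert(base))$matrix[1:3, 1:3]
      rot <- acos(max(-1, min(1, (sum(diag(Rrel)) - 1) / 2)))
      outs[[length(outs) + 1]] <- list(pose = pose, rms = out$rms_residual,
                                       rot = rot)
    }
    if (length(outs) == 0) {
      best0 <- base
    } else {
      rots <- vapply(outs, `[[`, numeric(1), "rot")
      rmss <- vapply(outs, `[[`, numeric(1), "rms")
      pool <- seq_along(outs)
      if (!is.null(trust) && any(rots <= trust)) pool <- which(rots <= trust)
      best0 <- outs[[pool[which.min(rmss[pool])]]]$pose
    }
    moved <- transform_mesh(frag$mesh, best0)
    out <- tryCatch(icp_register(moved, ffix, ...),
                    error = function(e)
                      stop(end, " fragment: ", conditionMessage(e), call. = FALSE))
    out$transform <- compose(out$transform, best0)
    out
  })
  list(m_prox = res[[1]]$transform, m_dist = res[[2]]$transform,
       prox_outcome = res[[1]], dist_outcome = res[[2]])
}

# Initial alignment + joint-end registration with flip arbitration: when
# initial_align reports a runner-up pose, both poses are carried through
# the fragment registrations and the one with the lower summed fragment
# RMS wins — fragment residuals separate a flipped whole-bone pose
# (stuck near the boundary-noise ceiling) from the true one far more
# sharply than any whole-bone score under a deformity.
align_and_register <- function(deformed, template, fraction = 0.2,
                               proximal = "-z", ...) {
  t0 <- initial_align(deformed, template)
  poses <- c(list(t0), attr(t0, "runner_up"))
  best <- NULL
  for (pose in poses) {
    attr(pose, "runner_up") <- NULL
    reg <- tryCatch(
      register_joint_ends(transform_mesh(deformed, pose), template,
                          fraction = fraction, proximal = proximal, ...),
      error = function(e) NULL)
    if (is.null(reg)) next
    score <- reg$prox_outcome$rms_residual + reg$dist_outcome$rms_residual
    if (is.null(best) || score < best$score)
      best <- list(t0 = pose, reg = reg, score = score)
  }
  if (is.null(best))
    stop("registration failed under every candidate alignment", call. = FALSE)
  best
}
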