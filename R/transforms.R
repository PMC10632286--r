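#' Rigid transforms and their Euler decomposition
#'
#' A rigid transform is stored as a 4x4 homogeneous matrix in millimetre
#' units: a proper rotation block (determinant +1) plus a translation column.
#' Reflections are never stored here; mirroring acts directly on meshes.
#'
#' @name rigid-transforms
NULL

#' Construct a rigid transform
#'
#' @param matrix 4x4 homogeneous matrix. The last row must be (0,0,0,1) and
#'   the 3x3 rotation block must be orthonormal with determinant +1.
#' @param tol orthonormality tolerance.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(matrix = diag(4), tol = 1e-6) {
  matrix <- unname(as.matrix(matrix))
  if (!all(dim(matrix) == c(4, 4)))
    stop("rigid transform must be a 4x4 matrix", call. = FALSE)
  if (!all(matrix[4, ] == c(0, 0, 0, 1)))
    stop("last row of a rigid transform must be (0,0,0,1)", call. = FALSE)
  R <- matrix[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol || det(R) < 0)
    stop("rotation block is not a proper rotation (orthonormal, det +1)",
         call. = FALSE)
  structure(list(matrix = matrix), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Build a rigid transform from a rotation matrix and translation vector
#' @param R 3x3 proper rotation matrix.
#' @param t length-3 translation, mm.
#' @export
rigid_from_rt <- function(R = diag(3), t = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t
  rigid_transform(m)
}

#' Elementary rotations about the x, y, z axes
#' @param theta angle in radians.
#' @name axis-rotations
NULL

#' @rdname axis-rotations
#' @export
rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}
#' @rdname axis-rotations
#' @export
rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}
#' @rdname axis-rotations
#' @export
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary unit axis (Rodrigues)
#' @param axis unit 3-vector.
#' @param theta angle, radians.
#' @export
rot_axis_angle <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Compose, invert, and difference rigid transforms
#'
#' `compose(a, b)` applies `b` first, then `a` (matrix product `a %*% b`).
#' `relative(a, b)` is the transform taking the frame reached by `a` to the
#' frame reached by `b`: `invert(a)` composed with `b`. This is the
#' difference operation used both for the realignment matrix
#' M = M_prox^-1 x M_dist and for between-method differences.
#'
#' @param a,b,m `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @name transform-algebra
NULL

as_rigid <- function(x) {
  if (inherits(x, "rigid_transform")) return(x)
  rigid_transform(x)
}

#' @rdname transform-algebra
#' @export
compose <- function(a, b) {
  a <- as_rigid(a); b <- as_rigid(b)
  rigid_transform(a$matrix %*% b$matrix)
}

#' @rdname transform-algebra
#' @export
invert <- function(m) {
  m <- as_rigid(m)
  R <- m$matrix[1:3, 1:3]
  t <- m$matrix[1:3, 4]
  rigid_from_rt(t(R), -crossprod(R, t)[, 1])
}

#' @rdname transform-algebra
#' @export
relative <- function(a, b) compose(invert(a), b)

#' Apply a rigid transform to points
#' @param m a `rigid_transform`.
#' @param pts Nx3 matrix of points (mm).
#' @return Nx3 matrix of transformed points.
#' @export
transform_points <- function(m, pts) {
  m <- as_rigid(m)
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts %*% t(m$matrix[1:3, 1:3]), 2, m$matrix[1:3, 4], `+`)
}

# Euler convention: fixed-axis X-then-Y-then-Z, i.e. R = Rz(phi_z) %*%
# Ry(phi_y) %*% Rx(phi_x). Chosen because the middle-angle domain
# [-pi/2, pi/2) matches this convention's restriction; held in one constant
# so it could be switched.
EULER_CONVENTION <- "xyz-fixed"

#' Decompose a rigid transform into translations and Euler angles
#'
#' Uses the fixed-axis X-Y-Z convention (R = Rz * Ry * Rx). Angle domains are
#' phi_x, phi_z in [-pi, pi) and phi_y in [-pi/2, pi/2). The totals are
#' T = sqrt(dx^2 + dy^2 + dz^2) and R = sqrt(phi_x^2 + phi_y^2 + phi_z^2).
#' Inputs within `gimbal_tol` of the |phi_y| = pi/2 singularity raise an
#' error rather than returning an ill-defined split of phi_x and phi_z.
#'
#' @param m a `rigid_transform`.
#' @param gimbal_tol closeness to the singularity treated as gimbal lock.
#' @return An object of class `euler_decomposition`: a list with fields
#'   `dx, dy, dz` (mm), `phi_x, phi_y, phi_z` (radians), and totals `T` (mm)
#'   and `R` (radians).
#' @export
decompose_euler <- function(m, gimbal_tol = 1e-9) {
  m <- as_rigid(m)
  R <- m$matrix[1:3, 1:3]
  t <- m$matrix[1:3, 4]
  # R = Rz*Ry*Rx gives R[3,1] = -sin(phi_y)
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  if (abs(abs(sy) - 1) < gimbal_tol)
    stop("gimbal lock: |phi_y| is at pi/2; Euler split of phi_x/phi_z is undefined",
         call. = FALSE)
  phi_y <- asin(sy)
  phi_x <- atan2(R[3, 2], R[3, 3])
  phi_z <- atan2(R[2, 1], R[1, 1])
  # fold the boundary of the half-open domains
  if (phi_x == pi) phi_x <- -pi
  if (phi_z == pi) phi_z <- -pi
  structure(list(
    dx = t[1], dy = t[2], dz = t[3],
    phi_x = phi_x, phi_y = phi_y, phi_z = phi_z,
    T = sqrt(sum(t^2)),
    R = sqrt(phi_x^2 + phi_y^2 + phi_z^2)
  ), class = "euler_decomposition")
}

#' @export
print.euler_decomposition <- function(x, ...) {
  cat(sprintf("<euler_decomposition> d = (%.3f, %.3f, %.3f) mm, phi = (%.4f, %.4f, %.4f) rad\n",
              x$dx, x$dy, x$dz, x$phi_x, x$phi_y, x$phi_z))
  cat(sprintf("  T = %.3f mm, R = %.4f rad\n", x$T, x$R))
  invisible(x)
}

#' Rebuild the rigid transform from an Euler decomposition
#' @param d an `euler_decomposition`.
#' @export
recompose_euler <- function(d) {
  R <- rot_z(d$phi_z) %*% rot_y(d$phi_y) %*% rot_x(d$phi_x)
  rigid_from_rt(R, c(d$dx, d$dy, d$dz))
}

#' Translational and rotational distance between two decompositions
#'
#' Component-wise Euclidean distances between the translation vectors
#' (Delta T, mm) and the Euler angle vectors (Phi R, radians) of two
#' realignments, the between-method difference measures of the evaluation.
#'
#' @param a,b `euler_decomposition` objects.
#' @return Named numeric vector `c(delta_T = , phi_R = )`.
#' @export
realignment_distance <- function(a, b) {
  dT <- sqrt((a$dx - b$dx)^2 + (a$dy - b$dy)^2 + (a$dz - b$dz)^2)
  pR <- sqrt((a$phi_x - b$phi_x)^2 + (a$phi_y - b$phi_y)^2 +
             (a$phi_z - b$phi_z)^2)
  c(delta_T = dT, phi_R = pR)
}

#' Serialize / deserialize a rigid transform as a row-major JSON array
#' @param m a `rigid_transform`.
#' @param path file path.
#' @export
write_transform_json <- function(m, path) {
  m <- as_rigid(m)
  jsonlite::write_json(apply(m$matrix, 1, function(r) r, simplify = FALSE),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  rows <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(rows)) rows <- do.call(rbind, rows)
  rigid_transform(matrix(as.numeric(t(rows)), 4, 4, byrow = TRUE))
}

#' Random proper rigid transform (for tests and simulations)
#' @param max_angle largest rotation magnitude, radians.
#' @param max_trans largest translation component, mm.
#' @export
random_rigid <- function(max_angle = pi / 3, max_trans = 20) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  rigid_from_rt(rot_axis_angle(ax, stats::runif(1, -max_angle, max_angle)),
                stats::runif(3, -max_trans, max_trans))
}
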