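# Quaternion arithmetic used throughout the package.
#
# Convention: unit quaternions are stored scalar-first (w, x, y, z), are
# right-handed, and represent frame rotations mapping local (sensor/segment)
# coordinates into the parent/world frame: v_world = R(q) %*% v_local.
# Vectorised routines accept an N x 4 matrix, one quaternion per row.

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 4L)
  storage.mode(q) <- "double"
  q
}

#' Normalize quaternions to unit length
#'
#' @param q numeric length-4 vector or N x 4 matrix, scalar-first.
#' @return Object of the same shape with unit rows.
#' @export
quat_normalize <- function(q) {
  vec <- is.null(dim(q))
  q <- as_quat_matrix(q)
  n <- sqrt(rowSums(q^2))
  if (any(n == 0)) stop("cannot normalize a zero quaternion")
  out <- q / n
  if (vec) drop(out) else out
}

#' Hamilton product of quaternions
#'
#' Both arguments may be single quaternions or N x 4 matrices (recycled
#' against each other row-wise).
#'
#' @param a,b quaternions, scalar-first.
#' @return quaternion(s) `a %*% b` in the same shape convention.
#' @export
quat_multiply <- function(a, b) {
  vec <- is.null(dim(a)) && is.null(dim(b))
  a <- as_quat_matrix(a); b <- as_quat_matrix(b)
  if (nrow(a) != nrow(b)) {
    if (nrow(a) == 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
    else if (nrow(b) == 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
    else stop("incompatible quaternion counts")
  }
  w <- a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4]
  x <- a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3]
  y <- a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2]
  z <- a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  out <- cbind(w, x, y, z, deparse.level = 0)
  if (vec) drop(out) else out
}

#' Quaternion conjugate (inverse for unit quaternions)
#' @param q quaternion(s), scalar-first.
#' @return conjugate with vector part negated.
#' @export
quat_conjugate <- function(q) {
  vec <- is.null(dim(q))
  q <- as_quat_matrix(q)
  out <- cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4], deparse.level = 0)
  if (vec) drop(out) else out
}

#' Rotate 3-vectors by unit quaternions
#'
#' @param q unit quaternion(s), scalar-first; rotation local -> world.
#' @param v length-3 vector or N x 3 matrix of local coordinates.
#' @return rotated coordinates, same shape as `v` (or expanded to N rows).
#' @export
quat_rotate <- function(q, v) {
  vec <- is.null(dim(v)) && is.null(dim(q))
  q <- as_quat_matrix(q)
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
  if (nrow(q) != nrow(v)) {
    if (nrow(q) == 1L) q <- q[rep(1L, nrow(v)), , drop = FALSE]
    else if (nrow(v) == 1L) v <- v[rep(1L, nrow(q)), , drop = FALSE]
    else stop("incompatible row counts")
  }
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  # v' = v + 2*w*(u x v) + 2*(u x (u x v)), u = vector part
  cx <- y * v[, 3] - z * v[, 2]
  cy <- z * v[, 1] - x * v[, 3]
  cz <- x * v[, 2] - y * v[, 1]
  ccx <- y * cz - z * cy
  ccy <- z * cx - x * cz
  ccz <- x * cy - y * cx
  out <- cbind(v[, 1] + 2 * (w * cx + ccx),
               v[, 2] + 2 * (w * cy + ccy),
               v[, 3] + 2 * (w * cz + ccz), deparse.level = 0)
  if (vec) drop(out) else out
}

#' Quaternion from rotation axis and angle
#' @param axis length-3 axis (need not be unit).
#' @param angle rotation angle in radians.
#' @return unit quaternion, scalar-first.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("axis must be non-zero")
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

#' Rotation-vector (axis-angle) chart
#'
#' `quat_to_rotvec` maps unit quaternions to rotation vectors (axis * angle,
#' radians, short arc); `quat_from_rotvec` is its inverse.
#'
#' @param q unit quaternion(s).
#' @return N x 3 matrix (or length-3 vector) of rotation vectors.
#' @export
quat_to_rotvec <- function(q) {
  vec <- is.null(dim(q))
  q <- as_quat_matrix(q)
  # force short arc
  flip <- q[, 1] < 0
  q[flip, ] <- -q[flip, , drop = FALSE]
  s <- sqrt(rowSums(q[, 2:4, drop = FALSE]^2))
  ang <- 2 * atan2(s, q[, 1])
  scale <- ifelse(s < 1e-12, 2, ang / pmax(s, 1e-300))
  out <- q[, 2:4, drop = FALSE] * scale
  if (vec) drop(out) else out
}

#' @rdname quat_to_rotvec
#' @param r rotation vector(s), length-3 or N x 3.
#' @export
quat_from_rotvec <- function(r) {
  vec <- is.null(dim(r))
  if (is.null(dim(r))) r <- matrix(r, ncol = 3L)
  ang <- sqrt(rowSums(r^2))
  half <- ang / 2
  k <- ifelse(ang < 1e-12, 0.5, sin(half) / pmax(ang, 1e-300))
  out <- cbind(cos(half), r * k, deparse.level = 0)
  if (vec) drop(out) else out
}

#' Geodesic angle between two orientations
#' @param a,b unit quaternions (vectors or N x 4 matrices).
#' @return angle(s) in radians in `[0, pi]`.
#' @export
quat_angle <- function(a, b) {
  d <- quat_multiply(quat_conjugate(a), b)
  d <- as_quat_matrix(d)
  ang <- 2 * atan2(sqrt(rowSums(d[, 2:4, drop = FALSE]^2)), abs(d[, 1]))
  if (length(ang) == 1L) ang[[1L]] else ang
}

#' Rotation matrix of a unit quaternion
#' @param q single unit quaternion, scalar-first.
#' @return 3 x 3 rotation matrix mapping local to world coordinates.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Unit quaternion of a rotation matrix
#' @param R 3 x 3 rotation matrix.
#' @return unit quaternion, scalar-first, with non-negative scalar part.
#' @export
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  if (q[1] < 0) q <- -q
  quat_normalize(q)
}

#' Spherical linear interpolation between two unit quaternions
#'
#' Antipodal pairs are resolved to the short arc (sign flip when the dot
#' product is negative), so the interpolation path is always the geodesic.
#'
#' @param qa,qb unit quaternions (endpoints at u = 0 and u = 1).
#' @param u interpolation fraction(s) in `[0, 1]`.
#' @return length-4 vector (single `u`) or N x 4 matrix of unit quaternions.
#' @export
quat_slerp <- function(qa, qb, u) {
  d <- sum(qa * qb)
  if (d < 0) { qb <- -qb; d <- -d }
  d <- min(d, 1)
  theta <- acos(d)
  if (theta < 1e-12) {
    out <- outer(1 - u, qa) + outer(u, qb)
  } else {
    s <- sin(theta)
    out <- outer(sin((1 - u) * theta) / s, qa) + outer(sin(u * theta) / s, qb)
  }
  out <- out / sqrt(rowSums(out^2))
  if (length(u) == 1L) drop(out) else out
}

# Identity quaternion
quat_identity <- function() c(1, 0, 0, 0)
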