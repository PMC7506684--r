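# Unit quaternions are length-4 numeric vectors c(w, x, y, z): scalar first,
# Hamilton convention, body-to-world. Euler angles are intrinsic Z-Y-X
# (yaw about vertical, then pitch about mediolateral, then roll about
# anterior-posterior), reported in degrees.

#' Construct a unit quaternion
#'
#' @param w,x,y,z Quaternion components (scalar first, Hamilton convention,
#'   body-to-world). The result is normalized.
#' @return Numeric vector `c(w, x, y, z)` with unit norm.
#' @export
quaternion <- function(w = 1, x = 0, y = 0, z = 0) {
  q <- c(w, x, y, z)
  if (!all(is.finite(q))) stop("quaternion components must be finite")
  quat_normalize(q)
}

#' Normalize a quaternion to unit norm
#'
#' @param q Numeric length-4 vector.
#' @return Unit quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero quaternion")
  q / n
}

#' Hamilton product of two quaternions
#'
#' Composes rotations: `quat_multiply(a, b)` first applies `b`, then `a`
#' (both body-to-world). The result is renormalized.
#'
#' @param a,b Unit quaternions `c(w, x, y, z)`.
#' @return Unit quaternion.
#' @export
quat_multiply <- function(a, b) {
  quat_normalize(c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  ))
}

#' Quaternion conjugate (inverse rotation for unit quaternions)
#'
#' @param q Unit quaternion.
#' @return Conjugate quaternion.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Rotate a 3-vector by a quaternion
#'
#' Applies the body-to-world rotation encoded by `q` to `v`
#' (i.e. \eqn{q \otimes (0,v) \otimes q^*}).
#'
#' @param q Unit quaternion.
#' @param v Numeric 3-vector.
#' @return Rotated 3-vector.
#' @export
quat_rotate <- function(q, v) {
  u <- q[2:4]
  t2 <- 2 * cross3(u, v)
  v + q[1] * t2 + cross3(u, t2)
}

# cross product, avoids the overhead of a general solution
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix of a quaternion
#'
#' @param q Unit quaternion (body-to-world).
#' @return 3x3 rotation matrix mapping body-frame vectors to the world frame.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Quaternion from an axis-angle rotation
#'
#' @param axis Rotation axis (3-vector, need not be unit).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) return(c(1, 0, 0, 0))
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

#' Euler angles (Z-Y-X intrinsic, degrees) to quaternion
#'
#' @param euler Numeric vector `c(roll, pitch, yaw)` in degrees. Roll is about
#'   the anterior-posterior (x) axis, pitch about the mediolateral (y) axis,
#'   yaw about the vertical (z) axis; applied intrinsically as yaw, pitch, roll.
#' @return Unit quaternion (body-to-world).
#' @export
euler_to_quat <- function(euler) {
  r <- euler * pi / 180
  qz <- quat_from_axis_angle(c(0, 0, 1), r[3])
  qy <- quat_from_axis_angle(c(0, 1, 0), r[2])
  qx <- quat_from_axis_angle(c(1, 0, 0), r[1])
  quat_multiply(quat_multiply(qz, qy), qx)
}

#' Quaternion to Euler angles (Z-Y-X intrinsic, degrees)
#'
#' At gimbal lock (|pitch| = 90 deg) yaw is set to 0 and roll absorbs the
#' remaining rotation.
#'
#' @param q Unit quaternion (body-to-world).
#' @return Numeric vector `c(roll, pitch, yaw)` in degrees with
#'   roll, yaw in (-180, 180] and pitch in [-90, 90].
#' @export
quat_to_euler <- function(q) {
  R <- quat_to_matrix(q)
  s <- -R[3, 1]
  if (abs(s) >= 1 - 1e-12) {
    # gimbal lock: only roll - sign(pitch)*yaw is defined; put it all in roll
    pitch <- sign(s) * pi / 2
    yaw <- 0
    roll <- atan2(-sign(s) * R[2, 3], R[2, 2])
  } else {
    pitch <- asin(s)
    roll <- atan2(R[3, 2], R[3, 3])
    yaw <- atan2(R[2, 1], R[1, 1])
  }
  c(roll = roll, pitch = pitch, yaw = yaw) * 180 / pi
}

#' Angle between two orientations
#'
#' Rotation angle of the error quaternion between two orientations.
#'
#' @param a,b Unit quaternions.
#' @return Angle in radians, in \[0, pi\].
#' @export
quat_angle <- function(a, b) {
  d <- min(1, abs(sum(a * b)))
  2 * acos(d)
}

# first-order (rectangular) quaternion propagation by a body rate over dt
quat_integrate_rate <- function(q, omega, dt) {
  dq <- 0.5 * quat_mult_raw(q, c(0, omega))
  quat_normalize(q + dt * dq)
}

# Hamilton product without renormalization (internal; used where the product
# is a rate, not a rotation)
quat_mult_raw <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

# Jacobian of R(q)^T v with respect to q (3x4), for gradient-based filters.
# R(q)^T v = (w^2 - u.u) v + 2 (u.v) u - 2 w (u x v), u = (x, y, z).
dquat_rot_inv_dq <- function(q, v) {
  w <- q[1]; u <- q[2:4]
  dw <- 2 * w * v - 2 * cross3(u, v)
  du <- -2 * tcrossprod(v, u) + 2 * tcrossprod(u, v) +
    2 * sum(u * v) * diag(3) + 2 * w * skew3(v)
  cbind(dw, du, deparse.level = 0)
}

skew3 <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), nrow = 3, byrow = TRUE)
}

# wrap angles in degrees to (-180, 180]
wrap_deg <- function(x) {
  y <- x - 360 * floor((x + 180) / 360)
  y[y == -180] <- 180
  y
}
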