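# Cane orientation estimators. World frame: x forward (north at zero yaw),
# y mediolateral, z up; gravity g_world = (0, 0, -9.81) m/s^2, so a static
# sensor measures specific force R^T (0,0,+9.81). The magnetic reference is
# a unit vector with a positive horizontal and negative vertical (downward
# dip) component.

GRAVITY <- 9.81

#' Closed-form orientation from accelerometer and magnetometer
#'
#' Assumes the accelerometer measures only gravity (cane static): tilt
#' (roll, pitch) follows from the measured gravity direction, and heading
#' (yaw) from the magnetometer after tilt compensation - the measured field
#' is rotated back into the horizontal plane by the estimated roll and
#' pitch, and yaw is the four-quadrant angle between its horizontal
#' component and the horizontal component of the reference field.
#'
#' @param acc Specific force 3-vector (ap, ml, v), m/s^2.
#' @param mag Magnetic field 3-vector (ap, ml, v), normalized units.
#' @param mag_reference World-frame magnetic field direction (default
#'   mid-latitude: horizontal north component with downward dip).
#' @return Numeric vector `c(roll, pitch, yaw)` in degrees (Z-Y-X intrinsic).
#' @export
accmag_orientation <- function(acc, mag,
                               mag_reference = c(0.4, 0, -0.9)) {
  an <- sqrt(sum(acc^2)); mn <- sqrt(sum(mag^2))
  if (an < .Machine$double.eps) stop("zero-norm accelerometer sample")
  if (mn < .Machine$double.eps) stop("zero-norm magnetometer sample")
  a <- acc / an
  roll <- atan2(a[2], a[3])
  pitch <- atan2(-a[1], sqrt(a[2]^2 + a[3]^2))
  # de-tilt the measured field: undo roll, then pitch
  cr <- cos(roll); sr <- sin(roll); cp <- cos(pitch); sp <- sin(pitch)
  m1 <- c(mag[1],
          cr * mag[2] - sr * mag[3],
          sr * mag[2] + cr * mag[3])
  mh <- c(cp * m1[1] + sp * m1[3],
          m1[2],
          -sp * m1[1] + cp * m1[3])
  yaw <- atan2(-mh[2], mh[1]) - atan2(-mag_reference[2], mag_reference[1])
  out <- wrap_deg(c(roll, pitch, yaw) * 180 / pi)
  names(out) <- c("roll", "pitch", "yaw")
  out
}

#' Madgwick filter state
#'
#' @param q Initial unit quaternion (body-to-world).
#' @param beta Filter gain in rad/s: the rate at which the gradient-descent
#'   correction pulls the gyro-integrated orientation toward the
#'   accelerometer/magnetometer solution. `beta = 0` is pure gyro
#'   integration.
#' @return Object of class `madgwick_state`.
#' @export
madgwick_state <- function(q = c(1, 0, 0, 0), beta = 0.1) {
  if (beta < 0) stop("beta must be non-negative")
  structure(list(q = quat_normalize(q), beta = beta), class = "madgwick_state")
}

#' One Madgwick filter update
#'
#' Integrates the gyroscope rate (first-order) and applies a normalized
#' gradient-descent step on the gravity (and, with `use_mag`, magnetic
#' field) alignment objective, weighted by the gain `beta`:
#' `q <- q + dt * (0.5 q (x) [0, w] - beta * grad f / ||grad f||)`, then
#' renormalization. A zero-norm accelerometer sample skips the corrective
#' step for that sample.
#'
#' @param state A [madgwick_state].
#' @param gyro Angular rate 3-vector, rad/s.
#' @param acc Specific force 3-vector, m/s^2.
#' @param mag Magnetic field 3-vector (ignored unless `use_mag`).
#' @param dt Time step, s.
#' @param use_mag Use the magnetometer (MARG variant) or gravity only.
#' @return The updated [madgwick_state].
#' @export
madgwick_update <- function(state, gyro, acc, mag = NULL, dt,
                            use_mag = TRUE) {
  stopifnot(inherits(state, "madgwick_state"))
  if (dt <= 0) stop("dt must be positive")
  q <- state$q
  qdot <- 0.5 * quat_mult_raw(q, c(0, gyro))
  grad <- c(0, 0, 0, 0)
  an <- sqrt(sum(acc^2))
  if (state$beta > 0 && an > .Machine$double.eps) {
    ahat <- acc / an
    f <- quat_rotate(quat_conjugate(q), c(0, 0, 1)) - ahat
    J <- dquat_rot_inv_dq(q, c(0, 0, 1))
    g4 <- as.vector(crossprod(J, f))
    if (use_mag && !is.null(mag)) {
      mn <- sqrt(sum(mag^2))
      if (mn > .Machine$double.eps) {
        mhat <- mag / mn
        hw <- quat_rotate(q, mhat)            # measured field in world frame
        bw <- c(sqrt(hw[1]^2 + hw[2]^2), 0, hw[3])  # reference: horizontal + dip
        fm <- quat_rotate(quat_conjugate(q), bw) - mhat
        Jm <- dquat_rot_inv_dq(q, bw)
        g4 <- g4 + as.vector(crossprod(Jm, fm))
      }
    }
    gn <- sqrt(sum(g4^2))
    # leave a numerically-zero gradient alone: normalizing it would turn
    # roundoff into a full-magnitude correction step (limit cycle)
    if (gn > 1e-12) grad <- g4 / gn
  }
  state$q <- quat_normalize(q + dt * (qdot - state$beta * grad))
  state
}

#' Error-state Kalman filter configuration
#'
#' Noise parameters of the 9-state indirect filter. Defaults match the
#' bundled simulator's sensor noise model.
#'
#' @param sigma_gyro Gyroscope white noise, rad/s (default 0.02).
#' @param sigma_acc Accelerometer white noise, m/s^2 (default 0.2).
#' @param sigma_bias Allowance for un-modelled slowly varying gyro bias,
#'   rad/s, added to the orientation process noise (default 0.01).
#' @param sigma_att Attitude aiding measurement noise on the normalized
#'   gravity/field direction components (default 0.025).
#' @param sigma_tip Tip-velocity pseudo-measurement noise during ground
#'   contact, m/s (default 0.01).
#' @param acc_gate Quasi-static gate: the gravity-direction update is only
#'   applied when | ||acc|| - g | is below this value, m/s^2 (default 0.5).
#' @return Object of class `ekf_config`.
#' @export
ekf_config <- function(sigma_gyro = 0.02, sigma_acc = 0.2, sigma_bias = 0.01,
                       sigma_att = 0.025, sigma_tip = 0.01, acc_gate = 0.5) {
  structure(list(sigma_gyro = sigma_gyro, sigma_acc = sigma_acc,
                 sigma_bias = sigma_bias, sigma_att = sigma_att,
                 sigma_tip = sigma_tip, acc_gate = acc_gate),
            class = "ekf_config")
}

#' Initialize the error-state Kalman filter
#'
#' The filter carries a nominal strapdown state (quaternion, velocity,
#' position) and the covariance of its 9-dimensional error
#' `[qe, ve, re]` (small-angle orientation error, velocity error, position
#' error). The error itself is kept at zero between updates: every
#' measurement update injects the estimated error into the nominal state
#' and resets it.
#'
#' @param q0 Initial orientation (unit quaternion).
#' @param cfg An [ekf_config].
#' @param p0_att,p0_vel,p0_pos Initial error standard deviations (rad, m/s, m).
#' @return Object of class `ekf_state`.
#' @export
ekf_init <- function(q0 = c(1, 0, 0, 0), cfg = ekf_config(),
                     p0_att = 0.1, p0_vel = 0.1, p0_pos = 0.1) {
  structure(list(q = quat_normalize(q0), v = c(0, 0, 0), p = c(0, 0, 0),
                 P = diag(c(rep(p0_att^2, 3), rep(p0_vel^2, 3), rep(p0_pos^2, 3))),
                 cfg = cfg),
            class = "ekf_state")
}

#' Error-state Kalman filter prediction step
#'
#' Propagates the nominal state by strapdown integration (orientation from
#' the gyro; velocity and position from the gravity-compensated specific
#' force) and the error covariance with the linearized error dynamics.
#'
#' @param state An [ekf_state].
#' @param gyro Angular rate 3-vector, rad/s.
#' @param acc Specific force 3-vector, m/s^2.
#' @param dt Time step, s.
#' @return The propagated [ekf_state].
#' @export
ekf_predict <- function(state, gyro, acc, dt) {
  stopifnot(inherits(state, "ekf_state"))
  if (dt <= 0) stop("dt must be positive")
  cfg <- state$cfg
  R <- quat_to_matrix(state$q)
  a_world <- R %*% acc + c(0, 0, -GRAVITY)
  state$p <- state$p + state$v * dt + 0.5 * as.vector(a_world) * dt^2
  state$v <- state$v + as.vector(a_world) * dt
  state$q <- quat_integrate_rate(state$q, gyro, dt)
  # linearized error dynamics:
  #   dqe/dt = -[w]x qe ; dve/dt = -R [acc]x qe ; dre/dt = ve
  A <- matrix(0, 9, 9)
  A[1:3, 1:3] <- -skew3(gyro)
  A[4:6, 1:3] <- -R %*% skew3(acc)
  A[7:9, 4:6] <- diag(3)
  Fm <- diag(9) + A * dt
  Qd <- diag(c(rep((cfg$sigma_gyro * dt)^2 + (cfg$sigma_bias * dt)^2, 3),
               rep((cfg$sigma_acc * dt)^2, 3),
               rep(1e-12, 3)))
  P <- Fm %*% state$P %*% t(Fm) + Qd
  state$P <- (P + t(P)) / 2
  state
}

# shared Kalman update on the 9-dim error state; injects and resets
ekf_apply_update <- function(state, H, innov, Rm) {
  S <- H %*% state$P %*% t(H) + Rm
  if (rcond(S) < 1e-14) stop("singular innovation covariance")
  K <- state$P %*% t(H) %*% solve(S)
  dx <- as.vector(K %*% innov)
  IKH <- diag(9) - K %*% H
  P <- IKH %*% state$P %*% t(IKH) + K %*% Rm %*% t(K)
  state$P <- (P + t(P)) / 2
  # inject: dq ~ [1, qe/2], then reset the error to zero
  state$q <- quat_normalize(quat_multiply(state$q, c(1, dx[1:3] / 2)))
  state$v <- state$v + dx[4:6]
  state$p <- state$p + dx[7:9]
  state
}

#' Ground-contact (tip pivot) measurement update
#'
#' During ground contact the cane tip is a fixed pivot, so the world-frame
#' tip velocity is zero. The predicted tip velocity
#' `v + R (w x b)` (sensor velocity plus the rotational term over the
#' sensor-to-tip lever arm `b = (0, 0, -sensor_offset)`) is the innovation
#' of a 3-dimensional pseudo-measurement.
#'
#' @param state An [ekf_state]; call only on samples labelled ground contact.
#' @param geometry A [cane_geometry].
#' @param gyro Current angular rate 3-vector, rad/s (defines the lever-arm
#'   velocity).
#' @return The updated [ekf_state].
#' @export
ekf_update_contact <- function(state, geometry, gyro) {
  stopifnot(inherits(state, "ekf_state"), inherits(geometry, "cane_geometry"))
  b <- c(0, 0, -geometry$sensor_offset)
  R <- quat_to_matrix(state$q)
  cvec <- cross3(gyro, b)
  v_tip <- state$v + as.vector(R %*% cvec)
  H <- matrix(0, 3, 9)
  H[, 1:3] <- -R %*% skew3(cvec)
  H[, 4:6] <- diag(3)
  Rm <- diag(3) * state$cfg$sigma_tip^2
  ekf_apply_update(state, H, -v_tip, Rm)
}

#' Attitude aiding update from gravity and magnetic field directions
#'
#' Treats the normalized accelerometer (gated on quasi-static samples) and
#' magnetometer readings as measurements of the world gravity and magnetic
#' field directions seen in the body frame.
#'
#' @param state An [ekf_state].
#' @param acc Specific force 3-vector, m/s^2.
#' @param mag Magnetic field 3-vector (or NULL to skip the field update).
#' @param mag_reference World-frame magnetic field direction.
#' @return The updated [ekf_state].
#' @export
ekf_update_attitude <- function(state, acc, mag = NULL,
                                mag_reference = c(0.4, 0, -0.9)) {
  stopifnot(inherits(state, "ekf_state"))
  cfg <- state$cfg
  R <- quat_to_matrix(state$q)
  H <- NULL; innov <- NULL
  an <- sqrt(sum(acc^2))
  if (an > .Machine$double.eps && abs(an - GRAVITY) < cfg$acc_gate) {
    zhat_b <- as.vector(t(R) %*% c(0, 0, 1))
    # measured gravity direction in body frame = +acc/|acc|
    Hg <- matrix(0, 3, 9); Hg[, 1:3] <- skew3(zhat_b)
    H <- Hg; innov <- acc / an - zhat_b
  }
  if (!is.null(mag)) {
    mn <- sqrt(sum(mag^2))
    if (mn > .Machine$double.eps) {
      mref <- mag_reference / sqrt(sum(mag_reference^2))
      mhat_b <- as.vector(t(R) %*% mref)
      Hm <- matrix(0, 3, 9); Hm[, 1:3] <- skew3(mhat_b)
      H <- rbind(H, Hm); innov <- c(innov, mag / mn - mhat_b)
    }
  }
  if (is.null(H)) return(state)
  Rm <- diag(length(innov)) * cfg$sigma_att^2
  ekf_apply_update(state, H, innov, Rm)
}

#' Estimate the cane orientation trajectory
#'
#' Runs one of the three estimators over a full IMU sequence and returns one
#' unit quaternion per sample. The initial orientation is the
#' accelerometer+magnetometer closed form on the first sample.
#'
#' * `"accmag"`: per-sample closed form (ignores `phase`).
#' * `"madgwick"`: gradient-descent complementary filter (ignores `phase`).
#' * `"ekf"`: error-state Kalman filter with attitude aiding every sample
#'   and the tip-pivot update on ground-contact samples (`phase` required).
#'
#' @param seq An [imu_sequence].
#' @param method One of `"accmag"`, `"madgwick"`, `"ekf"`.
#' @param phase A [phase_series] aligned to `seq` (required for `"ekf"`).
#' @param beta Madgwick gain, rad/s.
#' @param use_mag Use the magnetometer in the Madgwick filter.
#' @param cfg An [ekf_config] for the Kalman filter.
#' @param geometry A [cane_geometry] (tip lever arm of the pivot update).
#' @param mag_reference World-frame magnetic field direction.
#' @return An `n x 4` matrix of unit quaternions `(w, x, y, z)`, class
#'   `quat_trajectory`, with the method recorded in attribute `method`.
#' @export
estimate_orientation <- function(seq, method = c("madgwick", "accmag", "ekf"),
                                 phase = NULL, beta = 0.1, use_mag = TRUE,
                                 cfg = ekf_config(),
                                 geometry = cane_geometry(),
                                 mag_reference = c(0.4, 0, -0.9)) {
  method <- match.arg(method)
  n <- nrow(seq)
  acc <- imu_acc(seq); gyro <- imu_gyro(seq); mag <- imu_mag(seq)
  dt <- 1 / imu_fs(seq)
  out <- matrix(0, n, 4, dimnames = list(NULL, c("qw", "qx", "qy", "qz")))
  q0 <- euler_to_quat(accmag_orientation(acc[1, ], mag[1, ], mag_reference))
  if (method == "accmag") {
    for (i in seq_len(n))
      out[i, ] <- euler_to_quat(accmag_orientation(acc[i, ], mag[i, ], mag_reference))
  } else if (method == "madgwick") {
    st <- madgwick_state(q0, beta)
    out[1, ] <- st$q
    for (i in seq_len(n)[-1]) {
      st <- madgwick_update(st, gyro[i, ], acc[i, ], mag[i, ], dt, use_mag)
      out[i, ] <- st$q
    }
  } else {
    if (is.null(phase)) stop("the ekf method requires a phase series")
    if (length(phase) != n) stop("phase must be aligned to the sequence")
    contact <- is_contact(phase)
    st <- ekf_init(q0, cfg)
    st <- ekf_update_attitude(st, acc[1, ], mag[1, ], mag_reference)
    out[1, ] <- st$q
    for (i in seq_len(n)[-1]) {
      st <- ekf_predict(st, gyro[i, ], acc[i, ], dt)
      st <- ekf_update_attitude(st, acc[i, ], mag[i, ], mag_reference)
      if (contact[i]) st <- ekf_update_contact(st, geometry, gyro[i, ])
      out[i, ] <- st$q
    }
  }
  structure(out, method = method, class = c("quat_trajectory", "matrix", "array"))
}
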