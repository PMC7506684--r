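# shared fixtures: all synthetic, generated at test time

# noise list for ideal sensors
quiet_noise <- function() {
  list(acc = 0, gyro = 0, mag = 0, gyro_bias = 0,
       impact_acc = 0, impact_rate = 0, step_shake = 0)
}

noiseless_gait <- function(n_strides = 10, seed = 0, ...) {
  gait_params(n_strides = n_strides, noise = quiet_noise(), seed = seed, ...)
}

# small imu_sequence with analytic channels
toy_imu <- function(n = 30, fs = 100) {
  t <- (0:(n - 1)) / fs
  imu_sequence(t,
               acc = cbind(sin(t), cos(t), 9.81 + 0 * t),
               gyro = cbind(0.1 * t, -0.2 * t, 0 * t),
               mag = cbind(0.4 + 0 * t, 0 * t, -0.9 + 0 * t),
               fs = fs)
}

# independent strapdown oracle: exact axis-angle rotation-matrix composition
expmap_strapdown <- function(gyro, dt) {
  R <- diag(3)
  for (i in seq_len(nrow(gyro))) {
    w <- gyro[i, ]
    ang <- sqrt(sum(w^2)) * dt
    if (ang > 0) {
      u <- w / sqrt(sum(w^2))
      K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
                  3, 3, byrow = TRUE)
      R <- R %*% (diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K)
    }
  }
  R
}

rotation_angle_between <- function(q, R) {
  M <- quat_to_matrix(q)
  acos(pmin(1, pmax(-1, (sum(diag(crossprod(M, R))) - 1) / 2)))
}

# smooth band-limited random gyro signal at modest cane-like rates; the
# amplitude is capped so first-order integration truncation stays well
# below the equivalence tolerances these signals are used with
smooth_gyro <- function(n, fs = 100, sd = 0.3, max_amp = 0.35) {
  g <- matrix(0, n, 3)
  for (ax in 1:3) {
    f <- stats::runif(1, 0.2, 0.7)
    a <- max(-max_amp, min(max_amp, stats::rnorm(1, 0, sd)))
    ph <- stats::runif(1, 0, 2 * pi)
    g[, ax] <- a * sin(2 * pi * f * (1:n) / fs + ph)
  }
  g
}
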