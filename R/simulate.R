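# Synthetic cane-gait generator. The cane moves in the sagittal plane:
# during stance it pivots about the planted tip (inverted pendulum), during
# swing the tip translates forward while the shaft pitches back. The
# sagittal angular-velocity profile is built from smooth raised-cosine
# pulses: a dominant positive mid-swing (MS) peak flanked by smaller
# negative lobes near take-off (EC) and landing (IC), and a negative stance
# sweep. All kinematics are closed-form, so the returned angular velocity
# and specific force are exact derivatives of the orientation trajectory.

# raised-cosine pulse of half-width h centred at mu, its running integral,
# and its time derivative; all vectorized over t
pulse_val <- function(t, mu, h) {
  u <- (t - mu) / h
  ifelse(abs(u) < 1, cos(pi * u / 2)^2, 0)
}
pulse_int <- function(t, mu, h) {
  u <- pmin(1, pmax(-1, (t - mu) / h))
  h * (u / 2 + sin(pi * u) / (2 * pi) + 0.5)
}
pulse_der <- function(t, mu, h) {
  u <- (t - mu) / h
  ifelse(abs(u) < 1, -pi / (2 * h) * sin(pi * u), 0)
}

#' Cane-gait simulation parameters
#'
#' @param activity One of `"gait_2point"`, `"gait_3point"`, `"standing"`,
#'   `"sit_to_stand"`, `"stairs"`, `"carry"` (cane lifted and carried with a
#'   gentle arm-swing oscillation, no ground contact). For activities without
#'   strides the record duration is `n_strides * stride_period`.
#' @param stride_period Stride period, s.
#' @param contact_ratio Fraction of each stride spent in ground contact.
#' @param swing_amplitude Peak-to-peak sagittal pitch excursion, degrees;
#'   the pitch sweeps between +amplitude/2 and -amplitude/2.
#' @param n_strides Number of strides (or equivalent duration units).
#' @param fs Sampling rate, Hz.
#' @param noise List with elements `acc` (m/s^2), `gyro` (rad/s), `mag`
#'   (field units) white-noise standard deviations, `gyro_bias` (rad/s), the
#'   per-axis standard deviation of a constant gyro bias, and the impact
#'   transient model: `impact_acc` (m/s^2, typical amplitude of the short
#'   accelerometer shock at cane landing), `impact_rate` (1/s, rate of
#'   smaller micro-impacts from load shifts while the cane bears weight) and
#'   `step_shake` (m/s^2, amplitude of the decaying vibration rings that the
#'   user's footsteps transmit through body and ground to the loaded cane
#'   roughly twice per stride). Set every element to zero for ideal sensors.
#' @param mag_reference World-frame magnetic field direction (normalized
#'   internally; default mid-latitude with downward dip).
#' @param geometry A [cane_geometry].
#' @param step_length Tip advance per stride during swing, m.
#' @param lift_height Peak tip lift during swing, m.
#' @param step_rise Tip elevation gain per stride, m (used for `"stairs"`).
#' @param sweep_fraction Fraction of stance over which the pendulum sweep is
#'   concentrated (1 = the whole stance); the cane dwells nearly still in
#'   early stance, as a user loads the cane before stepping past it.
#' @param seed RNG seed for [synthesize_imu] / [make_cohort].
#' @return Object of class `gait_params`.
#' @export
gait_params <- function(activity = c("gait_2point", "gait_3point", "standing",
                                     "sit_to_stand", "stairs", "carry"),
                        stride_period = 1.0, contact_ratio = 0.6,
                        swing_amplitude = 20, n_strides = 10, fs = 100,
                        noise = list(acc = 0.2, gyro = 0.02, mag = 0.01,
                                     gyro_bias = 0.01, impact_acc = 6,
                                     impact_rate = 0.7, step_shake = 2.5,
                                     ring_freq = 9),
                        mag_reference = c(0.4, 0, -0.9),
                        geometry = cane_geometry(),
                        step_length = 0.4, lift_height = 0.03,
                        step_rise = 0.18, sweep_fraction = 0.6,
                        carry_freq = 1.1, carry_amp = 8, seed = 0) {
  activity <- match.arg(activity)
  if (stride_period <= 0) stop("stride_period must be positive")
  if (contact_ratio <= 0 || contact_ratio >= 1)
    stop("contact_ratio must lie strictly between 0 and 1")
  if (fs <= 0) stop("fs must be positive")
  if (sweep_fraction <= 0 || sweep_fraction > 1)
    stop("sweep_fraction must lie in (0, 1]")
  defaults <- list(acc = 0.2, gyro = 0.02, mag = 0.01, gyro_bias = 0.01,
                   impact_acc = 6, impact_rate = 0.7, step_shake = 2.5,
                   ring_freq = 9)
  noise <- utils::modifyList(defaults, as.list(noise))
  structure(list(activity = activity, stride_period = stride_period,
                 contact_ratio = contact_ratio,
                 swing_amplitude = swing_amplitude, n_strides = n_strides,
                 fs = fs, noise = noise,
                 mag_reference = mag_reference / sqrt(sum(mag_reference^2)),
                 geometry = geometry, step_length = step_length,
                 lift_height = lift_height, step_rise = step_rise,
                 sweep_fraction = sweep_fraction, carry_freq = carry_freq,
                 carry_amp = carry_amp, seed = seed),
            class = "gait_params")
}

# pulse table (amplitude, centre, half-width) for one gait stride; the IC
# lobe is placed 25 ms before and the EC lobe 15 ms after the force-defined
# phase boundaries - at landing the angular-rate trough precedes force
# loading, at take-off it follows force release.
gait_pulse_table <- function(p) {
  Tp <- p$stride_period; c_ <- p$contact_ratio; s <- (1 - c_) * Tp
  theta0 <- p$swing_amplitude / 2 * pi / 180
  h_l <- min(0.05, 0.12 * s)
  d_ec <- min(0.015, 0.3 * h_l); d_ic <- min(0.025, 0.5 * h_l)
  h_sw <- p$sweep_fraction * c_ * Tp / 2
  h_m <- 0.3 * s
  D <- 0.8 * 2 * theta0 / s
  P <- 2 * theta0 / h_sw
  A <- (2 * theta0 + 2 * D * h_l) / h_m
  data.frame(
    amp = c(-P, -D, -D, A),
    mu = c(c_ * Tp - h_sw, c_ * Tp + d_ec, Tp - d_ic, c_ * Tp + s / 2),
    h = c(h_sw, h_l, h_l, h_m)
  )
}

# sagittal pitch angle, rate and acceleration at wrapped stride times
gait_sagittal <- function(t_in, p) {
  Tp <- p$stride_period
  theta0 <- p$swing_amplitude / 2 * pi / 180
  tab <- gait_pulse_table(p)
  omega <- alpha <- numeric(length(t_in))
  theta <- rep(theta0, length(t_in))
  for (k in -1:1) {
    tk <- t_in + k * Tp
    for (j in seq_len(nrow(tab))) {
      omega <- omega + tab$amp[j] * pulse_val(tk, tab$mu[j], tab$h[j])
      alpha <- alpha + tab$amp[j] * pulse_der(tk, tab$mu[j], tab$h[j])
      theta <- theta + tab$amp[j] *
        (pulse_int(tk, tab$mu[j], tab$h[j]) - pulse_int(k * Tp, tab$mu[j], tab$h[j]))
    }
  }
  list(theta = theta, omega = omega, alpha = alpha)
}

#' Simulate ground-truth cane kinematics
#'
#' Generates the noise-free kinematic truth for one trial of the requested
#' activity: per-sample orientation quaternions, body-frame angular velocity
#' and specific force, sensor position/velocity, phase labels and a tip
#' reaction-force profile (a smooth bell peaking at 40 N during contact,
#' zero in swing, always above the 1 N labelling threshold while in
#' contact).
#'
#' @param params A [gait_params].
#' @return Object of class `gait_truth`: list with elements `t`, `q`
#'   (n x 4 quaternions, body-to-world), `omega` (n x 3 body rad/s), `acc`
#'   (n x 3 body specific force m/s^2), `vel`, `pos` (n x 3 world sensor
#'   velocity/position), `phase` ([phase_series]), `force` (N), `geometry`,
#'   `params`.
#' @export
simulate_cane <- function(params) {
  stopifnot(inherits(params, "gait_params"))
  p <- params
  Tp <- p$stride_period; c_ <- p$contact_ratio; s <- (1 - c_) * Tp
  fs <- p$fs
  n <- max(2L, round(p$n_strides * Tp * fs))
  t <- (0:(n - 1)) / fs
  r_s <- p$geometry$sensor_offset

  if (p$activity == "standing") {
    theta <- rep(5 * pi / 180, n); omega <- alpha <- numeric(n)
    contact <- rep(TRUE, n)
    force <- rep(30, n)
    tip <- list(x = numeric(n), z = numeric(n),
                vx = numeric(n), vz = numeric(n),
                ax = numeric(n), az = numeric(n))
  } else if (p$activity == "carry") {
    # cane lifted and carried: gentle arm-swing pitch oscillation, steady
    # forward translation, tip clear of the ground, no contact
    fa <- p$carry_freq; tha <- p$carry_amp * pi / 180
    theta <- tha * sin(2 * pi * fa * t)
    omega <- tha * 2 * pi * fa * cos(2 * pi * fa * t)
    alpha <- -tha * (2 * pi * fa)^2 * sin(2 * pi * fa * t)
    contact <- rep(FALSE, n)
    force <- numeric(n)
    v_carry <- 0.8
    tip <- list(x = v_carry * t, z = rep(0.05, n),
                vx = rep(v_carry, n), vz = numeric(n),
                ax = numeric(n), az = numeric(n))
  } else if (p$activity == "sit_to_stand") {
    # single smooth ramp from a forward lean to upright over the middle half
    dur <- p$n_strides * Tp
    tau <- pmin(1, pmax(0, (t / dur - 0.25) / 0.5))
    th0 <- 15 * pi / 180
    theta <- th0 * (1 + cos(pi * tau)) / 2
    omega <- -th0 * pi / 2 * sin(pi * tau) / (0.5 * dur)
    omega[tau <= 0 | tau >= 1] <- 0
    alpha <- -th0 * pi^2 / 2 * cos(pi * tau) / (0.5 * dur)^2
    alpha[tau <= 0 | tau >= 1] <- 0
    contact <- rep(TRUE, n)
    force <- 5 + 35 * tau
    tip <- list(x = numeric(n), z = numeric(n),
                vx = numeric(n), vz = numeric(n),
                ax = numeric(n), az = numeric(n))
  } else {
    # start the record 40 ms into quiet stance (cane already planted and
    # settled), past the landing lobe that straddles the stride boundary
    ts <- t + 0.04
    stride <- floor(ts / Tp + 1e-9)
    t_in <- ts - stride * Tp
    sag <- gait_sagittal(t_in, p)
    theta <- sag$theta; omega <- sag$omega; alpha <- sag$alpha
    contact <- t_in < c_ * Tp - 1e-9
    tau <- pmin(1, pmax(0, (t_in - c_ * Tp) / s))
    swing <- !contact
    L <- p$step_length
    dz <- if (p$activity == "stairs") p$step_rise else 0
    hl <- p$lift_height
    sig <- tau - sin(2 * pi * tau) / (2 * pi)
    sig1 <- (1 - cos(2 * pi * tau)) / s
    sig2 <- 2 * pi * sin(2 * pi * tau) / s^2
    tip <- list(
      x = stride * L + swing * L * sig,
      z = stride * dz + swing * (dz * sig + hl * sin(pi * tau)^2),
      vx = swing * L * sig1,
      vz = swing * (dz * sig1 + hl * pi * sin(2 * pi * tau) / s),
      ax = swing * L * sig2,
      az = swing * (dz * sig2 + hl * 2 * pi^2 * cos(2 * pi * tau) / s^2)
    )
    force <- ifelse(contact, 1.2 + 38.8 * sin(pi * pmax(0, t_in) / (c_ * Tp))^2, 0)
  }

  st <- sin(theta); ct <- cos(theta)
  pos <- cbind(tip$x + r_s * st, 0, tip$z + r_s * ct)
  vel <- cbind(tip$vx + r_s * omega * ct, 0, tip$vz - r_s * omega * st)
  acc_w <- cbind(tip$ax + r_s * (alpha * ct - omega^2 * st), 0,
                 tip$az - r_s * (alpha * st + omega^2 * ct))
  # body specific force: R^T (a_world - g_world), pure pitch => R = Ry(theta)
  fx <- acc_w[, 1]; fz <- acc_w[, 3] + GRAVITY
  acc_b <- cbind(ct * fx - st * fz, 0, st * fx + ct * fz)
  q <- cbind(cos(theta / 2), 0, sin(theta / 2), 0)
  colnames(q) <- c("qw", "qx", "qy", "qz")
  structure(list(t = t, q = q,
                 omega = cbind(0, omega, 0),
                 acc = acc_b, vel = vel, pos = pos,
                 phase = phase_series(contact), force = force,
                 geometry = p$geometry, params = p),
            class = "gait_truth")
}

#' @export
print.gait_truth <- function(x, ...) {
  cat(sprintf("<gait_truth> %s: %d samples at %g Hz, %.1f%% ground contact\n",
              x$params$activity, length(x$t), x$params$fs,
              100 * mean(is_contact(x$phase))))
  invisible(x)
}

#' Synthesize a noisy IMU recording from simulated truth
#'
#' Adds sensor imperfections to the kinematic truth: white noise on all
#' channels, a constant per-axis gyroscope bias drawn once per sequence,
#' and clipping to the sensor ranges (accelerometer +/- 5 g, gyroscope
#' +/- 1500 deg/s). The magnetometer measures the world reference field in
#' the body frame. Deterministic given `params$seed`.
#'
#' @param truth A `gait_truth` from [simulate_cane].
#' @param params A [gait_params] (defaults to the truth's own parameters).
#' @return An [imu_sequence] with the true tip force attached as `force_n`.
#' @export
synthesize_imu <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "gait_truth"))
  p <- params
  n <- length(truth$t)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(p$seed)
  bias <- stats::rnorm(3, 0, p$noise$gyro_bias)
  mag_b <- t(vapply(seq_len(n), function(i)
    quat_rotate(quat_conjugate(truth$q[i, ]), p$mag_reference),
    numeric(3)))
  acc <- truth$acc + matrix(stats::rnorm(3 * n, 0, p$noise$acc), n, 3)
  gyro <- sweep(truth$omega, 2, bias, `+`) +
    matrix(stats::rnorm(3 * n, 0, p$noise$gyro), n, 3)
  mag <- mag_b + matrix(stats::rnorm(3 * n, 0, p$noise$mag), n, 3)
  # impact transients: a short accelerometer shock at every cane landing and
  # sporadic micro-impacts (load shifts, grip adjustments) while the cane
  # bears weight; small accompanying gyro transient at landings
  contact <- is_contact(truth$phase)
  if (p$noise$impact_acc > 0) {
    decay <- c(1, 0.5, 0.25)
    add_burst <- function(M, i0, amp3, profile) {
      for (k in seq_along(profile)) {
        i <- i0 + k - 1L
        if (i <= n) M[i, ] <- M[i, ] + amp3 * profile[k]
      }
      M
    }
    landings <- which(diff(contact) == 1L) + 1L  # NC -> GC inside the record
    for (i0 in landings) {
      amp <- stats::rnorm(1, p$noise$impact_acc, p$noise$impact_acc / 4)
      dir <- c(stats::rnorm(1, 0, 0.4), stats::rnorm(1, 0, 0.2),
               -abs(stats::rnorm(1, 1, 0.2)))
      acc <- add_burst(acc, i0, amp * dir / sqrt(sum(dir^2)), decay)
      gyro <- add_burst(gyro, i0, stats::rnorm(3, 0, 0.15), decay[1:2])
    }
    if (p$noise$impact_rate > 0) {
      hit <- which(contact & stats::runif(n) < p$noise$impact_rate / p$fs)
      for (i0 in hit) {
        amp <- abs(stats::rnorm(1, 0.6 * p$noise$impact_acc,
                                0.2 * p$noise$impact_acc))
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        acc <- add_burst(acc, i0, amp * u, decay[1:2])
      }
    }
  }
  # footstep vibration: while the cane bears weight the user's steps ring
  # through body and ground into the shaft (~9 Hz, ~40 ms decay), roughly
  # every half stride; dominant on the vertical and sagittal channels
  if (p$noise$step_shake > 0) {
    ring_t <- (0:11) / p$fs
    ring <- exp(-ring_t / 0.04) * sin(2 * pi * p$noise$ring_freq * ring_t)
    blocks <- rle(contact)
    ends <- cumsum(blocks$lengths)
    starts <- ends - blocks$lengths + 1L
    for (bk in which(blocks$values)) {
      i <- starts[bk] + round(stats::runif(1, 0.1, 0.3) * p$fs)
      while (i <= ends[bk]) {
        amp <- abs(stats::rnorm(1, p$noise$step_shake,
                                0.3 * p$noise$step_shake))
        dir <- c(stats::rnorm(1, 0, 0.5), stats::rnorm(1, 0, 0.3),
                 sample(c(-1, 1), 1) * abs(stats::rnorm(1, 1, 0.2)))
        dir <- dir / sqrt(sum(dir^2))
        gdir <- c(stats::rnorm(1, 0, 0.3), sample(c(-1, 1), 1), 0)
        for (k in seq_along(ring)) {
          j <- i + k - 1L
          if (j > n) break
          acc[j, ] <- acc[j, ] + amp * ring[k] * dir
          gyro[j, ] <- gyro[j, ] + amp / 10 * ring[k] * gdir
        }
        i <- i + round(stats::runif(1, 0.45, 0.65) * p$fs)
      }
    }
  }
  acc <- pmin(pmax(acc, -5 * GRAVITY), 5 * GRAVITY)
  gyro <- pmin(pmax(gyro, -1500 * pi / 180), 1500 * pi / 180)
  imu_sequence(truth$t, acc, gyro, mag, fs = p$fs, force = truth$force)
}

#' Simulate a continuous multi-activity session
#'
#' Chains several activities into one continuous recording, the way an
#' instrumented-cane protocol is actually measured: quiet standing, a
#' sit-to-stand transfer, three-point gait, a stretch where the cane is
#' carried, two-point gait, a few stair steps, and a final stand. Each
#' segment reuses the subject's base parameters with mild activity-specific
#' adjustments (three-point and stair strides are slower with longer
#' contact). The truth and IMU streams of the segments are concatenated on a
#' common time base.
#'
#' @param base A [gait_params] describing the subject.
#' @param segments Optional list of per-segment overrides (each a named list
#'   with at least `activity` and `n_strides`); defaults to the protocol
#'   above.
#' @return `list(truth, imu)` where `truth` is a concatenated `gait_truth`
#'   and `imu` the matching noisy [imu_sequence]. Orientation is only
#'   piecewise continuous across segment boundaries; sessions are meant for
#'   phase-detection studies, single-activity trials for orientation
#'   studies.
#' @export
simulate_session <- function(base = gait_params(), segments = NULL) {
  stopifnot(inherits(base, "gait_params"))
  if (is.null(segments)) {
    segments <- list(
      list(activity = "standing", n_strides = 6),
      list(activity = "sit_to_stand", n_strides = 3),
      list(activity = "gait_3point", n_strides = 4,
           stride_period = base$stride_period * 1.15,
           contact_ratio = min(0.95, base$contact_ratio + 0.05)),
      list(activity = "carry", n_strides = 4),
      list(activity = "gait_2point", n_strides = 5),
      list(activity = "carry", n_strides = 3),
      list(activity = "stairs", n_strides = 3,
           stride_period = base$stride_period * 1.3,
           contact_ratio = min(0.95, base$contact_ratio + 0.05)),
      list(activity = "carry", n_strides = 3),
      list(activity = "standing", n_strides = 4)
    )
  }
  truths <- vector("list", length(segments))
  for (k in seq_along(segments)) {
    p <- utils::modifyList(base, segments[[k]])
    class(p) <- "gait_params"
    p$seed <- base$seed + k
    truths[[k]] <- simulate_cane(p)
  }
  fs <- base$fs
  offs <- 0; tt <- list()
  for (k in seq_along(truths)) {
    tt[[k]] <- truths[[k]]$t + offs
    offs <- offs + length(truths[[k]]$t) / fs
  }
  truth <- structure(list(
    t = unlist(tt),
    q = do.call(rbind, lapply(truths, `[[`, "q")),
    omega = do.call(rbind, lapply(truths, `[[`, "omega")),
    acc = do.call(rbind, lapply(truths, `[[`, "acc")),
    vel = do.call(rbind, lapply(truths, `[[`, "vel")),
    pos = do.call(rbind, lapply(truths, `[[`, "pos")),
    phase = phase_series(unlist(lapply(truths, function(x) is_contact(x$phase)))),
    force = unlist(lapply(truths, `[[`, "force")),
    geometry = base$geometry,
    params = {
      p <- base; p$activity <- "session"; p
    }), class = "gait_truth")
  list(truth = truth, imu = synthesize_imu(truth, base))
}

#' Simulate a multi-subject cohort
#'
#' Draws per-subject gait parameters by jittering a base parameter set
#' (uniform multiplicative jitter), then simulates truth and a noisy IMU
#' recording per subject. Deterministic given `seed`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param base A [gait_params] giving the cohort means.
#' @param variation Named list of relative jitter half-widths applied
#'   multiplicatively: `stride_period`, `swing_amplitude`, `contact_ratio`,
#'   `noise` (scales all noise terms together) and `morphology` (jointly
#'   jitters the per-subject signal morphology: footstep ring frequency,
#'   carry arm-swing frequency and amplitude, stance sweep shape, step
#'   length). A value of 0.1 draws from \[0.9, 1.1\] times the base value.
#'   Defaults reflect human-scale heterogeneity of cane users.
#' @param session If TRUE each subject's recording is a continuous
#'   multi-activity [simulate_session]; otherwise a single trial of
#'   `base$activity`.
#' @param seed Cohort RNG seed (default `base$seed`).
#' @return List with one element per subject: `list(id, params, truth, imu)`.
#' @export
make_cohort <- function(n_subjects, base = gait_params(),
                        variation = list(stride_period = 0.25,
                                         swing_amplitude = 0.3,
                                         contact_ratio = 0.1,
                                         noise = 0.3,
                                         morphology = 0.25),
                        session = FALSE, seed = base$seed) {
  if (n_subjects < 2L) stop("a cohort needs at least 2 subjects")
  defaults <- list(stride_period = 0, swing_amplitude = 0, contact_ratio = 0,
                   noise = 0, morphology = 0)
  jit <- utils::modifyList(defaults, as.list(variation))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  draw <- function(j) stats::runif(1, 1 - j, 1 + j)
  lapply(seq_len(n_subjects), function(i) {
    p <- base
    p$stride_period <- base$stride_period * draw(jit$stride_period)
    p$swing_amplitude <- base$swing_amplitude * draw(jit$swing_amplitude)
    p$contact_ratio <- min(0.95, base$contact_ratio * draw(jit$contact_ratio))
    nf <- draw(jit$noise)
    p$noise <- lapply(base$noise, function(x) x * nf)
    m <- jit$morphology
    p$noise$ring_freq <- base$noise$ring_freq * draw(m)
    p$carry_freq <- base$carry_freq * draw(m)
    p$carry_amp <- base$carry_amp * draw(m)
    p$sweep_fraction <- min(1, base$sweep_fraction * draw(m))
    p$step_length <- base$step_length * draw(m)
    p$seed <- (seed %% 1000000L) * 1000L + i
    if (session) {
      ses <- simulate_session(p)
      list(id = sprintf("S%02d", i), params = p, truth = ses$truth,
           imu = ses$imu)
    } else {
      truth <- simulate_cane(p)
      list(id = sprintf("S%02d", i), params = p, truth = truth,
           imu = synthesize_imu(truth, p))
    }
  })
}
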