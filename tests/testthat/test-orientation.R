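mag_ref <- c(0.4, 0, -0.9)

test_that("acc+mag closed form recovers canonical poses", {
  e <- accmag_orientation(c(0, 0, 9.81), mag_ref, mag_ref)
  expect_equal(unname(e), c(0, 0, 0), tolerance = 1e-9)
  # aAP = 0, aML = aV > 0: roll 45 deg
  e45 <- accmag_orientation(c(0, 5, 5), mag_ref, mag_ref)
  expect_equal(unname(e45["roll"]), 45, tolerance = 1e-9)
  # 90 deg yaw, level: rotate the reference field into the body frame
  q <- euler_to_quat(c(0, 0, 90))
  mb <- quat_rotate(quat_conjugate(q), mag_ref)
  ey <- accmag_orientation(c(0, 0, 9.81), mb, mag_ref)
  expect_equal(unname(ey["yaw"]), 90, tolerance = 1e-6)
  expect_error(accmag_orientation(c(0, 0, 0), mag_ref), "zero-norm")
  expect_error(accmag_orientation(c(0, 0, 9.81), c(0, 0, 0)), "zero-norm")
})

test_that("acc+mag recovers full attitude exactly on noiseless static poses", {
  set.seed(31)
  for (i in 1:50) {
    e <- c(runif(1, -170, 170), runif(1, -84, 84), runif(1, -170, 170))
    q <- euler_to_quat(e)
    acc <- quat_rotate(quat_conjugate(q), c(0, 0, 9.81))
    mb <- quat_rotate(quat_conjugate(q), mag_ref)
    got <- accmag_orientation(acc, mb, mag_ref)
    expect_equal(unname(got), e, tolerance = 1e-6)
  }
})

test_that("madgwick filter is stationary at equilibrium and integrates rates", {
  st <- madgwick_state(c(1, 0, 0, 0), beta = 0.1)
  st2 <- madgwick_update(st, c(0, 0, 0), c(0, 0, 9.81), mag_ref, 0.01)
  expect_equal(st2$q, st$q, tolerance = 1e-12)
  # beta = 0: constant rate (0,0,pi/2) for 1 s at dt = 0.001 -> 90 deg yaw
  st <- madgwick_state(c(1, 0, 0, 0), beta = 0)
  for (i in 1:1000)
    st <- madgwick_update(st, c(0, 0, pi / 2), c(0, 0, 9.81), NULL, 0.001, FALSE)
  expect_equal(unname(quat_to_euler(st$q)["yaw"]), 90, tolerance = 0.1)
  # zero accelerometer sample skips the corrective step (pure gyro)
  st <- madgwick_state(euler_to_quat(c(5, 0, 0)), beta = 0.5)
  st2 <- madgwick_update(st, c(0, 0, 0), c(0, 0, 0), mag_ref, 0.01)
  expect_equal(st2$q, st$q, tolerance = 1e-12)
  expect_error(madgwick_state(beta = -1), "non-negative")
  expect_error(madgwick_update(st, c(0, 0, 0), c(0, 0, 9.81), NULL, 0), "positive")
})

test_that("madgwick correction pulls a tilted estimate back to truth", {
  st <- madgwick_state(euler_to_quat(c(10, 0, 0)), beta = 0.1)
  errs <- numeric(500)
  for (i in 1:500) {
    st <- madgwick_update(st, c(0, 0, 0), c(0, 0, 9.81), mag_ref, 0.01)
    errs[i] <- quat_angle(st$q, c(1, 0, 0, 0)) * 180 / pi
  }
  expect_lt(errs[500], 0.5)
  above <- errs > 0.5
  expect_true(all(diff(errs[above]) < 0))  # strictly decreasing while converging
})

test_that("madgwick with beta=0 equals exp-map strapdown on smooth sequences", {
  set.seed(32)
  for (rep in 1:3) {
    gyro <- smooth_gyro(1000, 100, sd = 0.3)
    st <- madgwick_state(c(1, 0, 0, 0), beta = 0)
    for (i in 1:1000)
      st <- madgwick_update(st, gyro[i, ], c(0, 0, 9.81), NULL, 0.01, FALSE)
    R <- expmap_strapdown(gyro, 0.01)
    expect_lt(rotation_angle_between(st$q, R), 1e-6)
  }
})

test_that("estimators return unit quaternions, are deterministic, and hold static poses", {
  p <- gait_params(activity = "standing", n_strides = 3, noise = quiet_noise())
  tr <- simulate_cane(p); imu <- synthesize_imu(tr, p)
  for (m in c("accmag", "madgwick", "ekf")) {
    q1 <- estimate_orientation(imu, method = m, phase = tr$phase,
                               geometry = tr$geometry, mag_reference = p$mag_reference)
    expect_equal(nrow(q1), nrow(imu))
    expect_lt(max(abs(sqrt(rowSums(q1^2)) - 1)), 1e-6)
    q2 <- estimate_orientation(imu, method = m, phase = tr$phase,
                               geometry = tr$geometry, mag_reference = p$mag_reference)
    expect_identical(q1, q2)
    errs <- vapply(101:nrow(q1), function(i) quat_angle(q1[i, ], tr$q[i, ]) * 180 / pi,
                   numeric(1))
    expect_lt(max(errs), 0.1)
  }
  expect_error(estimate_orientation(imu, method = "nope"), "arg")
  expect_error(estimate_orientation(imu, method = "ekf"), "phase")
})

test_that("madgwick tracks simulated gait within a few degrees", {
  p <- gait_params(seed = 2)
  tr <- simulate_cane(p); imu <- synthesize_imu(tr, p)
  q <- estimate_orientation(imu, method = "madgwick",
                            mag_reference = p$mag_reference)
  expect_lt(orientation_rmse(q, tr$q)$total, 5)
})
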