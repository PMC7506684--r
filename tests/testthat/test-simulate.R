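test_that("gait truth has the declared structure and label balance", {
  p <- gait_params(stride_period = 1, contact_ratio = 0.6, fs = 100,
                   n_strides = 10, seed = 1)
  tr <- simulate_cane(p)
  expect_equal(length(tr$t), 1000L)
  expect_equal(sum(unclass(tr$phase)), 600L, tolerance = 10)
  expect_identical(unclass(label_from_force(tr$force)), unclass(tr$phase))
  expect_true(all(tr$force[unclass(tr$phase)] > 1))
  expect_true(all(tr$force[!unclass(tr$phase)] == 0))
  expect_error(gait_params(contact_ratio = 1.2), "between 0 and 1")
})

test_that("standing truth is exactly static", {
  tr <- simulate_cane(gait_params(activity = "standing", n_strides = 5))
  expect_lt(max(abs(sqrt(rowSums(tr$acc^2)) - 9.81)), 1e-9)
  expect_equal(max(abs(tr$omega)), 0)
  expect_true(all(unclass(tr$phase)))
})

test_that("angular velocity is the exact derivative of the orientation", {
  for (act in c("gait_2point", "gait_3point", "stairs", "sit_to_stand", "carry")) {
    p <- gait_params(activity = act, n_strides = 8, seed = 1)
    tr <- simulate_cane(p)
    q <- tr$q[1, ]
    for (i in 2:length(tr$t))
      q <- canekin:::quat_integrate_rate(q, tr$omega[i, ], 1 / p$fs)
    # first-order truncation grows with rate^3; carry oscillates fastest
    tol <- if (act == "carry") 0.5 else 0.2
    expect_lt(quat_angle(q, tr$q[length(tr$t), ]) * 180 / pi, tol)
  }
})

test_that("the planted tip is a fixed pivot during every contact sample", {
  p <- gait_params(n_strides = 6, seed = 2)
  tr <- simulate_cane(p)
  b <- c(0, 0, -p$geometry$sensor_offset)
  idx <- which(unclass(tr$phase))
  vt <- vapply(idx, function(i)
    sqrt(sum((tr$vel[i, ] + quat_rotate(tr$q[i, ],
                                        canekin:::cross3(tr$omega[i, ], b)))^2)),
    numeric(1))
  expect_lt(max(vt), 1e-9)
})

test_that("each swing carries exactly one dominant positive sagittal peak", {
  p <- noiseless_gait(n_strides = 7, seed = 3)
  tr <- simulate_cane(p)
  imu <- synthesize_imu(tr, p)
  ev <- detect_events(imu$gyr_ml, fs = p$fs)
  expect_equal(length(ev$ms), 7L)
  ph <- events_to_phase(ev, nrow(imu))
  interior <- 100:(nrow(imu) - 100)
  acc <- mean(unclass(ph)[interior] == unclass(tr$phase)[interior])
  expect_gt(acc, 0.95)
})

test_that("imu synthesis is seeded, faithful at zero noise, and clipped", {
  p <- noiseless_gait(n_strides = 3, seed = 5)
  tr <- simulate_cane(p)
  imu <- synthesize_imu(tr, p)
  expect_equal(unname(as.matrix(imu[, 2:4])), unname(tr$acc), tolerance = 1e-12)
  expect_equal(unname(as.matrix(imu[, 5:7])), unname(tr$omega), tolerance = 1e-12)
  expect_equal(imu$force_n, tr$force)
  p2 <- gait_params(n_strides = 3, seed = 7)
  tr2 <- simulate_cane(p2)
  a <- synthesize_imu(tr2, p2); b <- synthesize_imu(tr2, p2)
  expect_identical(as.matrix(a), as.matrix(b))
  expect_true(all(abs(as.matrix(a[, 2:4])) <= 5 * 9.81 + 1e-9))
  expect_true(all(abs(as.matrix(a[, 5:7])) <= 1500 * pi / 180 + 1e-9))
})

test_that("white-noise magnitudes match their configured levels", {
  p <- gait_params(activity = "standing", n_strides = 100, stride_period = 1,
                   noise = list(acc = 0, gyro = 0.02, mag = 0, gyro_bias = 0,
                                impact_acc = 0, impact_rate = 0, step_shake = 0),
                   seed = 8)
  tr <- simulate_cane(p)
  imu <- synthesize_imu(tr, p)
  resid <- as.matrix(imu[, 5:7]) - tr$omega
  expect_lt(abs(stats::sd(resid) - 0.02) / 0.02, 0.1)
})

test_that("cohorts are reproducible and respect the jitter spec", {
  c1 <- make_cohort(5, gait_params(n_strides = 2), seed = 0)
  c2 <- make_cohort(5, gait_params(n_strides = 2), seed = 0)
  expect_equal(length(c1), 5L)
  expect_identical(sapply(c1, `[[`, "id"), sapply(c2, `[[`, "id"))
  expect_identical(c1[[3]]$params, c2[[3]]$params)
  expect_equal(length(unique(sapply(c1, function(s) s$params$stride_period))), 5L)
  z <- make_cohort(3, gait_params(n_strides = 2),
                   variation = list(stride_period = 0, swing_amplitude = 0,
                                    contact_ratio = 0, noise = 0, morphology = 0),
                   seed = 1)
  expect_true(all(sapply(z, function(s) s$params$stride_period) == 1.0))
  j <- make_cohort(6, gait_params(n_strides = 2),
                   variation = list(stride_period = 0.1), seed = 2)
  sp <- sapply(j, function(s) s$params$stride_period)
  expect_true(all(sp >= 0.9 & sp <= 1.1))
  expect_error(make_cohort(1), "at least 2")
})

test_that("sessions concatenate activities into one consistent record", {
  ses <- simulate_session(gait_params(seed = 4))
  expect_equal(length(ses$truth$t), nrow(ses$imu))
  expect_equal(length(unclass(ses$truth$phase)), length(ses$truth$force))
  expect_lt(max(abs(diff(ses$truth$t) - 0.01)), 1e-9)
  expect_identical(unclass(label_from_force(ses$truth$force)),
                   unclass(ses$truth$phase))
  # contains both phases in quantity
  frac <- mean(unclass(ses$truth$phase))
  expect_gt(frac, 0.4); expect_lt(frac, 0.9)
})
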