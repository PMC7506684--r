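test_that("force labelling uses a strict 1 N threshold", {
  ph <- label_from_force(c(0, 0.5, 1.2, 3.0, 0.2))
  expect_equal(as.character(ph),
               c("no_contact", "no_contact", "contact", "contact", "no_contact"))
  expect_true(all(!unclass(label_from_force(rep(0, 10)))))
  expect_false(unclass(label_from_force(1.0))[1])    # exactly 1 N: no contact
  expect_true(unclass(label_from_force(1.0 + 1e-9))[1])
  expect_error(label_from_force(c(1, 2), threshold = -0.1), "non-negative")
  expect_error(label_from_force(c(1, NA)), "finite")
})

test_that("threshold detector implements the norm rule exactly", {
  mk <- function(acc, gyro) imu_sequence(0, matrix(acc, 1), matrix(gyro, 1),
                                         matrix(c(0.4, 0, -0.9), 1))
  cfg <- threshold_config(0.2, 0.3)
  expect_true(unclass(detect_phase_threshold(mk(c(0, 0, 9.81), c(0, 0, 0)), cfg)))
  expect_false(unclass(detect_phase_threshold(mk(c(0, 0, 10.31), c(0, 0, 0)), cfg)))
  expect_false(unclass(detect_phase_threshold(mk(c(0, 0, 9.81), c(0, 0.4, 0)), cfg)))
  # boundary: deviations exactly at the thresholds still count as contact
  expect_true(unclass(detect_phase_threshold(mk(c(0, 0, 9.81 + 0.2), c(0.3, 0, 0)), cfg)))
  expect_error(threshold_config(-1, 0.3), "positive")
})

test_that("threshold detector agrees with brute-force evaluation on random samples", {
  set.seed(11)
  n <- 1000
  acc <- matrix(rnorm(3 * n, 0, 4), n, 3); acc[, 3] <- acc[, 3] + 9.81
  gyro <- matrix(rnorm(3 * n, 0, 0.4), n, 3)
  seq <- imu_sequence((0:(n - 1)) / 100, acc, gyro, matrix(0.5, n, 3))
  got <- unclass(detect_phase_threshold(seq, threshold_config(0.2, 0.3)))
  want <- vapply(seq_len(n), function(j) {
    abs(sqrt(sum(acc[j, ]^2)) - 9.81) <= 0.2 && sqrt(sum(gyro[j, ]^2)) <= 0.3
  }, logical(1))
  expect_identical(got, want)
})

test_that("event detection finds MS and the flanking minima", {
  t <- seq(0, 1, by = 0.01)
  ev <- detect_events(-cos(2 * pi * t), fs = 100)
  expect_equal(ev$ms, 51L)          # t = 0.5
  expect_equal(ev$ec, 1L)           # t ~ 0
  expect_equal(ev$ic, 101L)         # t ~ 1
  expect_equal(length(detect_events(rep(0, 200))$ms), 0L)
  # truncated record: MS retained, no IC after it
  x <- -cos(2 * pi * t[1:55])
  ev2 <- detect_events(x, fs = 100)
  expect_equal(ev2$ms, 51L)
  expect_equal(length(ev2$ic), 0L)
  expect_equal(ev2$ec, 1L)
  # sub-prominence peaks are ignored
  expect_equal(length(detect_events(0.3 * -cos(2 * pi * t), fs = 100)$ms), 0L)
})

test_that("close MS peaks are merged keeping the larger", {
  t <- seq(0, 1.2, by = 0.01)
  x <- 1.0 * exp(-((t - 0.5) / 0.05)^2) + 0.8 * exp(-((t - 0.6) / 0.05)^2)
  ev <- detect_events(x, fs = 100, min_separation = 0.4)
  expect_equal(length(ev$ms), 1L)
  expect_lt(abs(ev$ms - 51L), 3L)
})

test_that("events map to contact intervals", {
  ev <- structure(list(ms = 35L, ic = 10L, ec = 60L), class = "event_set")
  ph <- unclass(events_to_phase(ev, 100))
  expect_true(all(ph[10:59])); expect_true(all(!ph[60:100])); expect_true(all(!ph[1:9]))
  # two strides
  ev2 <- structure(list(ms = integer(), ic = c(10L, 110L), ec = c(60L, 160L)),
                   class = "event_set")
  ph2 <- unclass(events_to_phase(ev2, 200))
  expect_true(all(ph2[c(10:59, 110:159)])); expect_true(all(!ph2[c(1:9, 60:109, 160:200)]))
  # before a first EC the implied state is contact
  ev3 <- structure(list(ms = integer(), ic = integer(), ec = 50L), class = "event_set")
  expect_true(all(unclass(events_to_phase(ev3, 100))[1:49]))
  # empty set: all no-contact
  expect_true(all(!unclass(events_to_phase(detect_events(rep(0, 50)), 50))))
  bad <- structure(list(ms = integer(), ic = c(10L, 20L), ec = integer()),
                   class = "event_set")
  expect_error(events_to_phase(bad, 100), "overlapping")
})

test_that("detect_events output always maps to valid intervals on noisy signals", {
  set.seed(12)
  for (i in 1:20) {
    x <- stats::filter(rnorm(400, 0, 1.2), rep(1 / 5, 5), sides = 1)
    x[is.na(x)] <- 0
    ev <- detect_events(as.numeric(x), fs = 100, min_prominence = 0.5,
                        min_separation = 0.2)
    expect_silent(events_to_phase(ev, 400))
  }
})

test_that("voting window takes the strict causal majority", {
  expect_true(all(unclass(voting_smooth(phase_series(rep(TRUE, 25))))[25]))
  # 13 contact of 25 is a majority; 12 is not
  raw13 <- phase_series(c(rep(TRUE, 13), rep(FALSE, 12)))
  raw12 <- phase_series(c(rep(TRUE, 12), rep(FALSE, 13)))
  expect_true(unclass(voting_smooth(raw13))[25])
  expect_false(unclass(voting_smooth(raw12))[25])
  # short bursts vanish entirely
  burst <- phase_series(c(rep(FALSE, 60), rep(TRUE, 5), rep(FALSE, 60)))
  expect_true(all(!unclass(voting_smooth(burst))))
  expect_error(voting_config(0), ">= 1")
})

test_that("voting smoothing matches brute-force majority at every index", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(30:120, 1)
    w <- sample(c(3, 10, 25), 1)
    raw <- runif(n) < runif(1, 0.2, 0.8)
    got <- unclass(voting_smooth(phase_series(raw), voting_config(w)))
    want <- vapply(seq_len(n), function(j) {
      win <- raw[max(1, j - w + 1):j]
      sum(win) > length(win) / 2
    }, logical(1))
    expect_identical(got, want)
  }
})

test_that("voting removes every sub-majority burst in long opposite context", {
  set.seed(14)
  for (i in 1:10) {
    len <- sample(1:12, 1)
    pos <- sample(40:80, 1)
    raw <- rep(FALSE, 150); raw[pos:(pos + len - 1)] <- TRUE
    sm <- unclass(voting_smooth(phase_series(raw), voting_config(25)))
    expect_true(all(!sm))
  }
})
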