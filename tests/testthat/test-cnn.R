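test_that("default architecture has exactly 745 trainable parameters", {
  m <- build_cnn()
  expect_equal(cnn_n_params(m), 745L)
  # per-layer: conv (3*6+1)*8, dense 72*8+8, dense 8+1
  expect_equal(length(m$conv_w) + length(m$conv_b), (3 * 6 + 1) * 8)
  expect_equal(length(m$fc1_w) + length(m$fc1_b), 72 * 8 + 8)
  expect_equal(length(m$fc2_w) + length(m$fc2_b), 8 + 1)
  expect_equal(m$arch$conv_out, 18L)   # no padding
  expect_error(build_cnn(window = 21), "incompatible")
})

test_that("zero-weight model outputs 0.5 and ties resolve to no contact", {
  m <- build_cnn("zero")
  W <- array(rnorm(5 * 20 * 6), dim = c(5, 20, 6))
  expect_equal(predict_cnn(m, W), rep(0.5, 5))
  seq <- toy_imu(30)
  expect_true(all(!unclass(predict_phase_cnn(m, seq))))
})

test_that("vectorized forward pass matches a naive per-window oracle", {
  set.seed(21)
  m <- build_cnn("glorot")
  W <- array(rnorm(4 * 20 * 6), dim = c(4, 20, 6))
  naive <- function(x) {   # x: 20 x 6
    conv <- matrix(0, 18, 8)
    for (p in 1:18) for (f in 1:8)
      conv[p, f] <- sum(x[p:(p + 2), ] * m$conv_w[, , f]) + m$conv_b[f]
    conv <- pmax(conv, 0)
    pool <- matrix(0, 9, 8)
    for (p in 1:9) for (f in 1:8)
      pool[p, f] <- max(conv[2 * p - 1, f], conv[2 * p, f])
    h <- pmax(as.vector(as.vector(pool) %*% m$fc1_w) + m$fc1_b, 0)
    stats::plogis(sum(h * as.vector(m$fc2_w)) + m$fc2_b)
  }
  got <- predict_cnn(m, W)
  for (k in 1:4) expect_equal(got[k], naive(W[k, , ]), tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(22)
  m <- build_cnn("glorot")
  W <- array(rnorm(3 * 20 * 6), dim = c(3, 20, 6))
  y <- c(1, 0, 1)
  loss <- function(model) {
    p <- pmin(pmax(canekin:::cnn_forward(model, W)$prob, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  fwd <- canekin:::cnn_forward(m, W, keep = TRUE)
  grad <- canekin:::cnn_backward(m, fwd, y)
  for (nm in c("conv_w", "conv_b", "fc1_w", "fc1_b", "fc2_w", "fc2_b")) {
    idx <- sample(length(m[[nm]]), min(5, length(m[[nm]])))
    for (i in idx) {
      mp <- m; mp[[nm]][i] <- mp[[nm]][i] + 1e-6
      mm <- m; mm[[nm]][i] <- mm[[nm]][i] - 1e-6
      expect_equal(grad[[nm]][i], (loss(mp) - loss(mm)) / 2e-6,
                   tolerance = 1e-4)
    }
  }
})

test_that("training is deterministic, rejects single-class labels and separates", {
  set.seed(23)
  n <- 200
  y <- rep(c(TRUE, FALSE), n / 2)
  W <- array(0, dim = c(n, 20, 6))
  for (k in seq_len(n)) {
    if (y[k]) {  # contact: gravity-dominated, quiet gyro
      W[k, , 1:3] <- rep(c(0, 0, 9.81), each = 20) + rnorm(60, 0, 0.2)
      W[k, , 4:6] <- rnorm(60, 0, 0.05)
    } else {     # swing: large sagittal rate, perturbed specific force
      W[k, , 1:3] <- rep(c(2, 0, 8), each = 20) + rnorm(60, 0, 1)
      W[k, , 5] <- 2.5 + rnorm(20, 0, 0.3)
      W[k, , c(4, 6)] <- rnorm(40, 0, 0.3)
    }
  }
  tr_idx <- 1:140; te_idx <- 141:200
  m1 <- train_cnn(W[tr_idx, , ], y[tr_idx], epochs = 20, seed = 0)
  m2 <- train_cnn(W[tr_idx, , ], y[tr_idx], epochs = 20, seed = 0)
  expect_identical(m1$conv_w, m2$conv_w)
  expect_identical(m1$fc1_w, m2$fc1_w)
  acc <- mean((predict_cnn(m1, W[te_idx, , ]) > 0.5) == y[te_idx])
  expect_gt(acc, 0.9)
  expect_true(is.finite(attr(m1, "final_loss")))
  expect_error(train_cnn(W[1:10, , ], rep(TRUE, 10)), "single class")
})

test_that("per-sample prediction is causal with a no-contact warm-up", {
  p <- noiseless_gait(n_strides = 2, seed = 1)
  seq <- synthesize_imu(simulate_cane(p), p)
  m <- build_cnn("zero"); m$fc2_b <- 5   # constant 'contact' model
  ph <- unclass(predict_phase_cnn(m, seq))
  expect_equal(length(ph), nrow(seq))
  expect_true(all(!ph[1:19]))
  expect_true(all(ph[20:length(ph)]))
  expect_error(predict_phase_cnn(build_cnn(), toy_imu(19)), "shorter")
})

test_that("model files round-trip weights and architecture", {
  set.seed(24)
  m <- build_cnn("glorot")
  path <- tempfile(fileext = ".json")
  write_cnn(m, path)
  m2 <- read_cnn(path)
  expect_equal(m2$conv_w, m$conv_w)
  expect_equal(m2$fc1_w, m$fc1_w)
  expect_equal(m2$fc2_b, m$fc2_b)
  W <- array(rnorm(3 * 20 * 6), dim = c(3, 20, 6))
  expect_equal(predict_cnn(m2, W), predict_cnn(m, W))
  expect_error(read_cnn({p <- tempfile(); jsonlite::write_json(list(a = 1), p); p}),
               "not a canekin")
})
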