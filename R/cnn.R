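# The ground-contact phase classifier: a deliberately tiny 1D CNN sized for
# real-time inference on embedded hardware.
#
#   input 20 x 6 (20 samples x acc/gyro channels)
#   -> 1D convolution along time, 8 filters, kernel 3, no padding  (18 x 8), ReLU
#   -> max pooling, size 2                                          (9 x 8)
#   -> flatten                                                      (72)
#   -> dense 8, ReLU
#   -> dense 1, sigmoid  (probability of ground contact)
#
# Trainable parameters: (3*6+1)*8 + (72*8+8) + (8+1) = 152 + 584 + 9 = 745.
# Forward and backward passes are vectorized over the window batch; training
# uses mini-batch Adam on binary cross-entropy.

#' Build the ground-contact phase CNN
#'
#' Constructs the default architecture (see package vignette) with 745
#' trainable parameters.
#'
#' @param init Weight initialization: `"glorot"` (uniform Glorot/Xavier,
#'   drawn from the current RNG state) or `"zero"`.
#' @param window Input window length in samples (default 20).
#' @param n_channels Number of input channels (default 6).
#' @param n_filters Convolution filters (default 8).
#' @param kernel Convolution kernel length (default 3).
#' @param pool Max-pooling size (default 2).
#' @param n_dense Neurons in the hidden dense layer (default 8).
#' @return Object of class `cnn_model`: a list of weight arrays
#'   (`conv_w` kernel x channel x filter, `conv_b`, `fc1_w`, `fc1_b`,
#'   `fc2_w`, `fc2_b`) plus the architecture descriptor.
#' @export
build_cnn <- function(init = c("glorot", "zero"), window = 20, n_channels = 6,
                      n_filters = 8, kernel = 3, pool = 2, n_dense = 8) {
  init <- match.arg(init)
  conv_out <- window - kernel + 1L
  if (conv_out < 1L || conv_out %% pool != 0L)
    stop("window, kernel and pool sizes are incompatible")
  n_flat <- (conv_out %/% pool) * n_filters
  glorot <- function(fan_in, fan_out, dims) {
    lim <- sqrt(6 / (fan_in + fan_out))
    array(stats::runif(prod(dims), -lim, lim), dim = dims)
  }
  zero <- function(dims) array(0, dim = dims)
  mk <- if (init == "glorot") glorot else function(a, b, dims) zero(dims)
  model <- list(
    conv_w = mk(kernel * n_channels, conv_out * n_filters, c(kernel, n_channels, n_filters)),
    conv_b = numeric(n_filters),
    fc1_w = mk(n_flat, n_dense, c(n_flat, n_dense)),
    fc1_b = numeric(n_dense),
    fc2_w = mk(n_dense, 1, c(n_dense, 1)),
    fc2_b = 0,
    arch = list(window = window, n_channels = n_channels, n_filters = n_filters,
                kernel = kernel, pool = pool, n_dense = n_dense,
                conv_out = conv_out, n_flat = n_flat)
  )
  class(model) <- "cnn_model"
  model
}

#' Number of trainable parameters of a CNN model
#'
#' @param model A `cnn_model`.
#' @return Integer parameter count (745 for the default architecture).
#' @export
cnn_n_params <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  sum(vapply(model[c("conv_w", "conv_b", "fc1_w", "fc1_b", "fc2_w", "fc2_b")],
             length, integer(1)))
}

#' @export
print.cnn_model <- function(x, ...) {
  a <- x$arch
  cat(sprintf(paste0(
    "<cnn_model> %dx%d input -> conv(%d filters, kernel %d) -> pool(%d) ",
    "-> dense(%d) -> dense(1, sigmoid); %d parameters\n"),
    a$window, a$n_channels, a$n_filters, a$kernel, a$pool, a$n_dense,
    cnn_n_params(x)))
  invisible(x)
}

# Vectorized forward pass over a batch of windows.
# windows: N x window x channels array. Returns intermediates for backprop.
cnn_forward <- function(model, windows, keep = FALSE) {
  a <- model$arch
  N <- dim(windows)[1]
  Wc <- matrix(model$conv_w, nrow = a$kernel * a$n_channels)  # (kernel*ch) x filters
  Z1 <- array(0, dim = c(N, a$conv_out, a$n_filters))
  Xp <- vector("list", if (keep) a$conv_out else 0L)
  for (p in seq_len(a$conv_out)) {
    M <- windows[, p:(p + a$kernel - 1L), , drop = FALSE]
    dim(M) <- c(N, a$kernel * a$n_channels)
    Z1[, p, ] <- sweep(M %*% Wc, 2, model$conv_b, `+`)
    if (keep) Xp[[p]] <- M
  }
  A1 <- pmax(Z1, 0)
  half <- a$conv_out %/% a$pool
  odd <- A1[, seq(1, a$conv_out, by = 2), , drop = FALSE]
  even <- A1[, seq(2, a$conv_out, by = 2), , drop = FALSE]
  P <- pmax(odd, even)
  Fl <- P
  dim(Fl) <- c(N, a$n_flat)
  Z2 <- sweep(Fl %*% model$fc1_w, 2, model$fc1_b, `+`)
  A2 <- pmax(Z2, 0)
  logits <- as.vector(A2 %*% model$fc2_w) + model$fc2_b
  prob <- stats::plogis(logits)
  if (!keep) return(list(prob = prob))
  list(prob = prob, logits = logits, A2 = A2, Fl = Fl,
       mask_pool = odd >= even, A1 = A1, Xp = Xp)
}

#' Ground-contact probability for a batch of windows
#'
#' @param model A `cnn_model`.
#' @param windows `N x window x 6` array (see [sliding_windows]).
#' @return Numeric vector of N probabilities in \[0, 1\].
#' @export
predict_cnn <- function(model, windows) {
  stopifnot(inherits(model, "cnn_model"))
  if (length(dim(windows)) == 2L)
    windows <- array(windows, dim = c(1L, dim(windows)))
  a <- model$arch
  if (dim(windows)[2] != a$window || dim(windows)[3] != a$n_channels)
    stop(sprintf("windows must be N x %d x %d", a$window, a$n_channels))
  cnn_forward(model, windows)$prob
}

# Backward pass; returns gradients matching the weight list layout.
cnn_backward <- function(model, fwd, y) {
  a <- model$arch
  N <- length(y)
  dlogit <- matrix((fwd$prob - y) / N, ncol = 1)         # d(mean BCE)/dlogit
  dW3 <- crossprod(fwd$A2, dlogit)
  db3 <- sum(dlogit)
  dA2 <- dlogit %*% t(model$fc2_w)
  dA2[fwd$A2 <= 0] <- 0
  dW2 <- crossprod(fwd$Fl, dA2)
  db2 <- colSums(dA2)
  dFl <- dA2 %*% t(model$fc1_w)
  half <- a$conv_out %/% a$pool
  dP <- array(dFl, dim = c(N, half, a$n_filters))
  dA1 <- array(0, dim = c(N, a$conv_out, a$n_filters))
  m <- fwd$mask_pool
  dA1[, seq(1, a$conv_out, by = 2), ] <- dP * m
  dA1[, seq(2, a$conv_out, by = 2), ] <- dP * (1 - m)
  dA1[fwd$A1 <= 0] <- 0
  dWc <- matrix(0, nrow = a$kernel * a$n_channels, ncol = a$n_filters)
  dbc <- numeric(a$n_filters)
  for (p in seq_len(a$conv_out)) {
    dZp <- dA1[, p, , drop = TRUE]
    if (is.null(dim(dZp))) dZp <- matrix(dZp, nrow = N)
    dWc <- dWc + crossprod(fwd$Xp[[p]], dZp)
    dbc <- dbc + colSums(dZp)
  }
  list(conv_w = array(dWc, dim = dim(model$conv_w)), conv_b = dbc,
       fc1_w = dW2, fc1_b = db2, fc2_w = dW3, fc2_b = db3)
}

#' Train the phase CNN
#'
#' Mini-batch Adam on binary cross-entropy. Training is deterministic given
#' `seed` (weight initialization and epoch shuffling both derive from it).
#'
#' @param windows `N x 20 x 6` array of training windows.
#' @param labels [phase_series] (or logical vector) of length N: the contact
#'   phase at each window's last sample.
#' @param epochs Training epochs (default 30).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 64).
#' @param seed RNG seed (default 0).
#' @param model Optionally a `cnn_model` to continue training; by default a
#'   fresh Glorot-initialized default architecture.
#' @param verbose Print the loss once per epoch.
#' @return The trained `cnn_model`, with attributes `final_loss` (mean
#'   training BCE of the last epoch) and `loss_history`.
#' @export
train_cnn <- function(windows, labels, epochs = 30, lr = 1e-3,
                      batch_size = 64, seed = 0, model = NULL,
                      verbose = FALSE) {
  y <- if (inherits(labels, "phase_series")) is_contact(labels) else as.logical(labels)
  N <- dim(windows)[1]
  if (length(y) != N) stop("one label per window required")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class; both phases are required")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  if (is.null(model)) model <- build_cnn("glorot")
  y <- as.numeric(y)
  par_names <- c("conv_w", "conv_b", "fc1_w", "fc1_b", "fc2_w", "fc2_b")
  m <- lapply(model[par_names], function(p) p * 0)
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; n_seen <- 0
    for (start in seq(1L, N, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, N)]
      wb <- windows[idx, , , drop = FALSE]
      yb <- y[idx]
      fwd <- cnn_forward(model, wb, keep = TRUE)
      p <- pmin(pmax(fwd$prob, 1e-12), 1 - 1e-12)
      ep_loss <- ep_loss - sum(yb * log(p) + (1 - yb) * log(1 - p))
      n_seen <- n_seen + length(idx)
      grad <- cnn_backward(model, fwd, yb)
      step <- step + 1
      for (nm in par_names) {
        m[[nm]] <- b1 * m[[nm]] + (1 - b1) * grad[[nm]]
        v[[nm]] <- b2 * v[[nm]] + (1 - b2) * grad[[nm]]^2
        mhat <- m[[nm]] / (1 - b1^step)
        vhat <- v[[nm]] / (1 - b2^step)
        model[[nm]] <- model[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    history[ep] <- ep_loss / n_seen
    if (verbose) message(sprintf("epoch %d/%d: loss %.4f", ep, epochs, history[ep]))
  }
  attr(model, "final_loss") <- history[epochs]
  attr(model, "loss_history") <- history
  model
}

#' Per-sample phase prediction with the CNN
#'
#' Causal: the label of sample j uses only samples j-19 ... j. A sample is
#' ground contact iff the model probability strictly exceeds 0.5 (ties are
#' no contact). The first 19 samples, for which no full window exists, are
#' labelled no contact (warm-up policy).
#'
#' @param model A `cnn_model`.
#' @param seq An [imu_sequence] with at least 20 samples.
#' @return A [phase_series] of the same length as `seq`.
#' @export
predict_phase_cnn <- function(model, seq) {
  a <- model$arch
  W <- sliding_windows(seq, n = a$window)
  prob <- predict_cnn(model, W)
  phase_series(c(rep(FALSE, a$window - 1L), prob > 0.5))
}

#' Save CNN weights and architecture to a JSON file
#'
#' @param model A `cnn_model`.
#' @param path Output path (JSON with an architecture manifest and flat
#'   weight arrays).
#' @return Invisibly, `path`.
#' @export
write_cnn <- function(model, path) {
  stopifnot(inherits(model, "cnn_model"))
  payload <- list(
    format = "canekin-cnn-1",
    arch = model$arch,
    weights = lapply(model[c("conv_w", "conv_b", "fc1_w", "fc1_b",
                             "fc2_w", "fc2_b")],
                     function(p) list(dim = dim(p), data = as.vector(p)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load CNN weights saved by [write_cnn]
#'
#' @param path Path to the JSON model file.
#' @return A `cnn_model`.
#' @export
read_cnn <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "canekin-cnn-1"))
    stop("not a canekin CNN model file: ", path)
  a <- payload$arch
  model <- build_cnn("zero", window = a$window, n_channels = a$n_channels,
                     n_filters = a$n_filters, kernel = a$kernel,
                     pool = a$pool, n_dense = a$n_dense)
  for (nm in names(payload$weights)) {
    w <- payload$weights[[nm]]
    model[[nm]] <- if (is.null(w$dim) || length(w$dim) < 2) as.vector(w$data)
    else array(w$data, dim = w$dim)
  }
  model$fc2_b <- as.numeric(model$fc2_b)
  model
}
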