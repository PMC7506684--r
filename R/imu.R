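# IMU streams are held as an "imu_sequence": a data.frame of uniformly sampled
# 9-axis samples plus the sampling rate. Body-frame axis convention throughout:
# x = anterior-posterior (ap), y = mediolateral (ml), z = vertical (v, up).
# Units: seconds, m/s^2, rad/s; magnetometer in normalized field units.

IMU_COLS <- c("t", "acc_ap", "acc_ml", "acc_v",
              "gyr_ap", "gyr_ml", "gyr_v",
              "mag_ap", "mag_ml", "mag_v")

#' Construct an IMU sequence
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param acc n x 3 specific force, m/s^2 (columns ap, ml, v).
#' @param gyro n x 3 angular rate, rad/s.
#' @param mag n x 3 magnetic field, normalized units.
#' @param fs Sampling rate in Hz (default 100).
#' @param force Optional per-sample cane-tip reaction force in N.
#' @return An object of class `imu_sequence`: a data.frame with columns
#'   `t, acc_ap, acc_ml, acc_v, gyr_ap, gyr_ml, gyr_v, mag_ap, mag_ml, mag_v`
#'   (plus `force_n` when supplied) and attribute `fs`.
#' @export
imu_sequence <- function(t, acc, gyro, mag, fs = 100, force = NULL) {
  acc <- as_n_by_3(acc, "acc"); gyro <- as_n_by_3(gyro, "gyro")
  mag <- as_n_by_3(mag, "mag")
  n <- length(t)
  if (n < 1L) stop("an imu_sequence needs at least one sample")
  if (nrow(acc) != n || nrow(gyro) != n || nrow(mag) != n)
    stop("t, acc, gyro and mag must have matching lengths")
  if (!all(is.finite(t), is.finite(acc), is.finite(gyro), is.finite(mag)))
    stop("IMU samples must be finite")
  if (n > 1L && any(diff(t) <= 0))
    stop("timestamps must be strictly increasing")
  df <- data.frame(t = t,
                   acc_ap = acc[, 1], acc_ml = acc[, 2], acc_v = acc[, 3],
                   gyr_ap = gyro[, 1], gyr_ml = gyro[, 2], gyr_v = gyro[, 3],
                   mag_ap = mag[, 1], mag_ml = mag[, 2], mag_v = mag[, 3])
  if (!is.null(force)) {
    if (length(force) != n) stop("force must have one value per sample")
    df$force_n <- force
  }
  structure(df, fs = fs, class = c("imu_sequence", "data.frame"))
}

as_n_by_3 <- function(x, what) {
  x <- as.matrix(x)
  if (is.null(dim(x)) || ncol(x) == 1L) x <- matrix(x, ncol = 3, byrow = TRUE)
  if (ncol(x) != 3L) stop(sprintf("%s must have 3 columns", what))
  storage.mode(x) <- "double"
  x
}

#' @export
print.imu_sequence <- function(x, ...) {
  cat(sprintf("<imu_sequence> %d samples at %g Hz (%.2f s)%s\n",
              nrow(x), imu_fs(x), nrow(x) / imu_fs(x),
              if ("force_n" %in% names(x)) ", with tip force" else ""))
  invisible(x)
}

#' Sampling rate of an IMU sequence
#' @param seq An `imu_sequence`.
#' @return Sampling rate in Hz.
#' @export
imu_fs <- function(seq) attr(seq, "fs")

# accessors used throughout: plain matrices
imu_acc <- function(seq) as.matrix(seq[, c("acc_ap", "acc_ml", "acc_v")])
imu_gyro <- function(seq) as.matrix(seq[, c("gyr_ap", "gyr_ml", "gyr_v")])
imu_mag <- function(seq) as.matrix(seq[, c("mag_ap", "mag_ml", "mag_v")])

#' Cane geometry
#'
#' @param shaft_length Tip-to-handle length of the cane shaft, m.
#' @param sensor_offset Distance from the tip to the IMU along the shaft, m.
#' @return Object of class `cane_geometry`.
#' @export
cane_geometry <- function(shaft_length = 0.9, sensor_offset = 0.75) {
  if (shaft_length <= 0) stop("shaft_length must be positive")
  if (sensor_offset < 0 || sensor_offset > shaft_length)
    stop("sensor_offset must lie within [0, shaft_length]")
  structure(list(shaft_length = shaft_length, sensor_offset = sensor_offset),
            class = "cane_geometry")
}

#' Read an IMU log from CSV
#'
#' Expects a comma-separated file with header
#' `t,acc_ap,acc_ml,acc_v,gyr_ap,gyr_ml,gyr_v,mag_ap,mag_ml,mag_v` and an
#' optional `force_n` column. Non-uniform timestamps are linearly resampled
#' onto a uniform grid at `fs`.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz the stream is (re)sampled at.
#' @param units Either `"si"` (m/s^2, rad/s; the package convention) or
#'   `"g_deg"` (accelerometer in g, gyroscope in deg/s; converted on read).
#' @return An [imu_sequence].
#' @export
read_imu_csv <- function(path, fs = 100, units = c("si", "g_deg")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("malformed CSV: ", conditionMessage(e)))
  missing <- setdiff(IMU_COLS, names(df))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "))
  if (nrow(df) < 1L) stop("empty IMU file: ", path)
  if (anyNA(df[IMU_COLS]) || !all(vapply(df[IMU_COLS], is.numeric, TRUE)))
    stop("non-numeric or missing values in IMU columns")
  if (nrow(df) > 1L && any(diff(df$t) <= 0))
    stop("timestamps must be strictly increasing")
  acc <- as.matrix(df[, c("acc_ap", "acc_ml", "acc_v")])
  gyro <- as.matrix(df[, c("gyr_ap", "gyr_ml", "gyr_v")])
  if (units == "g_deg") {
    acc <- acc * 9.81
    gyro <- gyro * pi / 180
  }
  force <- if ("force_n" %in% names(df)) df$force_n else NULL
  seq <- imu_sequence(df$t, acc, gyro,
                      as.matrix(df[, c("mag_ap", "mag_ml", "mag_v")]),
                      fs = fs, force = force)
  resample_uniform(seq, fs)
}

#' Resample an IMU sequence onto a uniform time grid
#'
#' Linear interpolation of every channel onto `t[1] + (0:(n-1))/fs`. A
#' sequence already uniform at `fs` (to 1e-6 s) is returned unchanged.
#'
#' @param seq An [imu_sequence].
#' @param fs Target sampling rate, Hz.
#' @return A uniformly sampled [imu_sequence].
#' @export
resample_uniform <- function(seq, fs = imu_fs(seq)) {
  t <- seq$t
  n <- length(t)
  if (n > 1L) {
    dt <- diff(t)
    if (all(abs(dt - 1 / fs) < 1e-6)) {
      attr(seq, "fs") <- fs
      return(seq)
    }
  }
  tg <- t[1] + (0:(max(1L, floor((t[n] - t[1]) * fs + 1e-9)))) / fs
  tg <- tg[tg <= t[n] + 1e-12]
  cols <- setdiff(names(seq), "t")
  out <- data.frame(t = tg)
  for (cl in cols) out[[cl]] <- stats::approx(t, seq[[cl]], xout = tg)$y
  imu_sequence(out$t,
               out[, c("acc_ap", "acc_ml", "acc_v")],
               out[, c("gyr_ap", "gyr_ml", "gyr_v")],
               out[, c("mag_ap", "mag_ml", "mag_v")],
               fs = fs,
               force = if ("force_n" %in% names(out)) out$force_n else NULL)
}

#' Write an IMU sequence to CSV
#'
#' Values are written with enough digits that
#' `read_imu_csv(write_imu_csv(seq))` reproduces `seq` to better than 1e-9
#' relative tolerance.
#'
#' @param seq An [imu_sequence].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_imu_csv <- function(seq, path) {
  if (dir.exists(path)) stop("path is a directory: ", path)
  df <- as.data.frame(seq)
  out <- tryCatch(
    utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                       path, sep = ",", quote = FALSE, row.names = FALSE),
    error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)),
    warning = function(w) stop("cannot write ", path, ": ", conditionMessage(w)))
  invisible(path)
}

#' Static calibration of an IMU sequence
#'
#' Over a stationary interval, estimates the gyroscope bias as the per-axis
#' mean and subtracts it from the whole record, and rescales the
#' accelerometer so that the mean specific-force norm over the interval
#' equals g = 9.81 m/s^2. Idempotent on its own output.
#'
#' @param seq An [imu_sequence].
#' @param interval Integer sample index range (e.g. `1:100`) during which the
#'   cane was stationary; at least 10 samples.
#' @param g Gravity magnitude, m/s^2.
#' @return The calibrated [imu_sequence], with attributes `gyro_bias` and
#'   `acc_scale` recording the applied correction.
#' @export
calibrate_static <- function(seq, interval, g = 9.81) {
  interval <- as.integer(interval)
  if (length(interval) < 10L)
    stop("calibration interval must contain at least 10 samples")
  if (min(interval) < 1L || max(interval) > nrow(seq))
    stop("calibration interval out of range")
  gyro <- imu_gyro(seq)
  bias <- colMeans(gyro[interval, , drop = FALSE])
  acc <- imu_acc(seq)
  norm_mean <- mean(sqrt(rowSums(acc[interval, , drop = FALSE]^2)))
  if (norm_mean < .Machine$double.eps)
    stop("zero accelerometer norm over calibration interval")
  scale <- g / norm_mean
  out <- imu_sequence(seq$t,
                      acc * scale,
                      sweep(gyro, 2, bias),
                      imu_mag(seq),
                      fs = imu_fs(seq),
                      force = if ("force_n" %in% names(seq)) seq$force_n else NULL)
  attr(out, "gyro_bias") <- bias
  attr(out, "acc_scale") <- scale
  out
}

#' Causal sliding windows over the 6 inertial channels
#'
#' Window `j` (one per sample index from `n` onward, 1-based) stacks samples
#' `j-n+1 ... j` of the accelerometer and gyroscope channels, so every window
#' contains only past and current samples.
#'
#' @param seq An [imu_sequence] with at least `n` samples.
#' @param n Window length in samples (default 20).
#' @return A `(len - n + 1) x n x 6` array; `[k, , ]` is the window labelling
#'   sample `n + k - 1`. Channel order: acc ap/ml/v then gyro ap/ml/v.
#'   Attribute `index` gives the labelled sample index of each window.
#' @export
sliding_windows <- function(seq, n = 20) {
  len <- nrow(seq)
  if (n < 1L) stop("window length must be >= 1")
  if (len < n) stop(sprintf("sequence of %d samples is shorter than the %d-sample window", len, n))
  S <- cbind(imu_acc(seq), imu_gyro(seq))
  nw <- len - n + 1L
  idx <- outer(seq_len(nw), 0:(n - 1L), `+`)   # nw x n matrix of row indices
  W <- array(S[as.vector(idx), , drop = FALSE], dim = c(nw, n, 6L))
  attr(W, "index") <- n:len
  W
}
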