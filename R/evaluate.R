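# Validation metrics and protocols: sample-wise phase accuracy, per-axis
# orientation RMSE, leave-one-subject-out cross-validation, and side-by-side
# method comparisons.

#' Sample-wise phase accuracy
#'
#' Percent of samples on which two phase series agree.
#'
#' @param pred,truth [phase_series] objects of equal length.
#' @return Accuracy in percent (0-100).
#' @export
phase_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("phase series must have equal length")
  100 * mean(is_contact(pred) == is_contact(truth))
}

#' Orientation RMSE report
#'
#' Per-axis root-mean-square error between two quaternion trajectories.
#' Errors are computed per sample on the Z-Y-X Euler angles, wrapped to
#' (-180, 180] before squaring. `total` pools the three per-axis error
#' streams (total^2 = mean of all squared axis errors); `angle` is the RMSE
#' of the rotation angle of the per-sample error quaternion.
#'
#' @param pred_q,truth_q `n x 4` matrices of unit quaternions.
#' @return Object of class `rmse_report`: list with `roll`, `pitch`, `yaw`,
#'   `total`, `angle`, all in degrees.
#' @export
orientation_rmse <- function(pred_q, truth_q) {
  pred_q <- as.matrix(pred_q); truth_q <- as.matrix(truth_q)
  if (nrow(pred_q) != nrow(truth_q))
    stop("trajectories must have equal length")
  n <- nrow(pred_q)
  err <- matrix(0, n, 3)
  ang <- numeric(n)
  for (i in seq_len(n)) {
    err[i, ] <- wrap_deg(quat_to_euler(pred_q[i, ]) - quat_to_euler(truth_q[i, ]))
    ang[i] <- quat_angle(pred_q[i, ], truth_q[i, ]) * 180 / pi
  }
  structure(list(roll = sqrt(mean(err[, 1]^2)),
                 pitch = sqrt(mean(err[, 2]^2)),
                 yaw = sqrt(mean(err[, 3]^2)),
                 total = sqrt(mean(err^2)),
                 angle = sqrt(mean(ang^2))),
            class = "rmse_report")
}

#' @export
print.rmse_report <- function(x, ...) {
  cat(sprintf(
    "<rmse_report> roll %.3f  pitch %.3f  yaw %.3f  total %.3f deg (angle %.3f)\n",
    x$roll, x$pitch, x$yaw, x$total, x$angle))
  invisible(x)
}

# windows + per-window labels for one subject (window labels the last sample)
subject_windows <- function(subj, window = 20) {
  W <- sliding_windows(subj$imu, n = window)
  idx <- attr(W, "index")
  list(W = W, y = is_contact(subj$truth$phase)[idx])
}

#' Leave-one-subject-out cross-validation of the CNN detector
#'
#' One fold per subject: the CNN is trained on the windows of all other
#' subjects and evaluated sample-wise on the held-out subject (with and
#' without the voting-window smoother). Deterministic given `seed`.
#'
#' @param cohort A cohort from [make_cohort].
#' @param epochs,lr,batch_size Training configuration (see [train_cnn]).
#' @param voting A [voting_config] for the smoothed variant.
#' @param seed Training seed.
#' @return A data.frame with one row per fold: `subject`, `accuracy_cnn`,
#'   `accuracy_cnn_voting` (percent).
#' @export
loso_cv <- function(cohort, epochs = 10, lr = 1e-3, batch_size = 64,
                    voting = voting_config(), seed = 0) {
  if (length(cohort) < 2L) stop("leave-one-subject-out needs >= 2 subjects")
  data <- lapply(cohort, subject_windows)
  res <- lapply(seq_along(cohort), function(k) {
    train <- do.call(rbind, lapply(data[-k], function(d) {
      dim(d$W) <- c(dim(d$W)[1], prod(dim(d$W)[2:3]))
      d$W
    }))
    dim(train) <- c(nrow(train), 20L, 6L)
    y_train <- unlist(lapply(data[-k], `[[`, "y"))
    model <- train_cnn(train, y_train, epochs = epochs, lr = lr,
                       batch_size = batch_size, seed = seed)
    pred <- predict_phase_cnn(model, cohort[[k]]$imu)
    truth <- cohort[[k]]$truth$phase
    data.frame(subject = cohort[[k]]$id,
               accuracy_cnn = phase_accuracy(pred, truth),
               accuracy_cnn_voting =
                 phase_accuracy(voting_smooth(pred, voting), truth))
  })
  do.call(rbind, res)
}

#' Compare phase-detection methods on a cohort
#'
#' Evaluates the requested detectors on every subject: the threshold and
#' event detectors run directly on each subject's recording; the CNN (and
#' its voting-smoothed variant) is evaluated under leave-one-subject-out
#' cross-validation so a subject is never scored by a model that saw its
#' data.
#'
#' @param cohort A cohort from [make_cohort].
#' @param methods Subset of `c("threshold", "event", "cnn", "cnn_voting")`.
#' @param threshold_cfg A [threshold_config].
#' @param voting A [voting_config].
#' @param epochs,seed CNN training configuration.
#' @return A data.frame `method, mean, sd` (accuracy percent across
#'   subjects), with the per-subject matrix in attribute `per_subject`.
#' @export
compare_phase_methods <- function(cohort,
                                  methods = c("threshold", "event", "cnn",
                                              "cnn_voting"),
                                  threshold_cfg = threshold_config(),
                                  voting = voting_config(),
                                  epochs = 10, seed = 0) {
  known <- c("threshold", "event", "cnn", "cnn_voting")
  if (length(methods) < 1L || !all(methods %in% known))
    stop("unknown method; choose from ", paste(known, collapse = ", "))
  acc <- matrix(NA_real_, length(cohort), length(methods),
                dimnames = list(vapply(cohort, `[[`, "", "id"), methods))
  for (i in seq_along(cohort)) {
    subj <- cohort[[i]]
    truth <- subj$truth$phase
    if ("threshold" %in% methods)
      acc[i, "threshold"] <- phase_accuracy(
        detect_phase_threshold(subj$imu, threshold_cfg), truth)
    if ("event" %in% methods) {
      ev <- detect_events(subj$imu$gyr_ml, fs = imu_fs(subj$imu))
      acc[i, "event"] <- phase_accuracy(
        events_to_phase(ev, length(truth)), truth)
    }
  }
  if (any(c("cnn", "cnn_voting") %in% methods)) {
    folds <- loso_cv(cohort, epochs = epochs, voting = voting, seed = seed)
    if ("cnn" %in% methods) acc[, "cnn"] <- folds$accuracy_cnn
    if ("cnn_voting" %in% methods)
      acc[, "cnn_voting"] <- folds$accuracy_cnn_voting
  }
  out <- data.frame(method = methods,
                    mean = apply(acc, 2, mean),
                    sd = apply(acc, 2, stats::sd),
                    row.names = NULL)
  attr(out, "per_subject") <- acc
  out
}

#' Compare orientation estimators on simulated trials
#'
#' Runs each estimator on each trial and reports the mean and standard
#' deviation of the total orientation RMSE across trials. The error-state
#' Kalman filter consumes the trial's true phase labels.
#'
#' @param trials List of trials, each `list(truth, imu)` (e.g. cohort
#'   entries or single simulations).
#' @param methods Subset of `c("accmag", "madgwick", "ekf")`.
#' @param beta Madgwick gain.
#' @param cfg An [ekf_config].
#' @return A data.frame `method, mean, sd` (total RMSE, degrees), with the
#'   per-trial matrix in attribute `per_trial`.
#' @export
compare_orientation_methods <- function(trials,
                                        methods = c("accmag", "madgwick", "ekf"),
                                        beta = 0.1, cfg = ekf_config()) {
  known <- c("accmag", "madgwick", "ekf")
  if (length(methods) < 1L || !all(methods %in% known))
    stop("unknown method; choose from ", paste(known, collapse = ", "))
  rmse <- matrix(NA_real_, length(trials), length(methods),
                 dimnames = list(NULL, methods))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    mag_ref <- tr$truth$params$mag_reference
    geom <- tr$truth$geometry
    for (m in methods) {
      q <- estimate_orientation(tr$imu, method = m, phase = tr$truth$phase,
                                beta = beta, cfg = cfg, geometry = geom,
                                mag_reference = mag_ref)
      rmse[i, m] <- orientation_rmse(q, tr$truth$q)$total
    }
  }
  out <- data.frame(method = methods,
                    mean = apply(rmse, 2, mean),
                    sd = apply(rmse, 2, stats::sd),
                    row.names = NULL)
  attr(out, "per_trial") <- rmse
  out
}
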