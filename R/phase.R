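# Ground-contact phase series and the two classical detectors: the norm
# threshold rule and the sagittal gyroscope gait-event method, plus the
# causal majority-voting smoother.

PHASE_LEVELS <- c("no_contact", "contact")

#' Construct a phase series
#'
#' A per-sample binary label sequence: `"contact"` (cane tip on the ground)
#' or `"no_contact"` (cane moving through the air).
#'
#' @param x Logical vector (TRUE = ground contact), or character vector with
#'   values `"contact"` / `"no_contact"`.
#' @return Object of class `phase_series`: a logical vector (TRUE = contact).
#' @export
phase_series <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    if (!all(x %in% PHASE_LEVELS)) stop("phase labels must be 'contact' or 'no_contact'")
    x <- x == "contact"
  }
  if (!is.logical(x)) stop("phase labels must be logical or contact/no_contact strings")
  if (anyNA(x)) stop("phase labels must not be missing")
  structure(as.logical(x), class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d samples, %.1f%% ground contact\n",
              length(x), 100 * mean(unclass(x))))
  invisible(x)
}

#' @export
as.character.phase_series <- function(x, ...) {
  ifelse(unclass(x), "contact", "no_contact")
}

#' @export
`[.phase_series` <- function(x, i) phase_series(unclass(x)[i])

is_contact <- function(phase) {
  stopifnot(inherits(phase, "phase_series"))
  unclass(phase)
}

#' Label ground contact from tip reaction force
#'
#' A sample is in ground contact when the measured tip reaction force
#' strictly exceeds the threshold (default 1 N); a force exactly at the
#' threshold is no contact.
#'
#' @param force Per-sample reaction force, N.
#' @param threshold Force threshold, N (default 1).
#' @return A [phase_series].
#' @export
label_from_force <- function(force, threshold = 1.0) {
  if (threshold < 0) stop("force threshold must be non-negative")
  if (!all(is.finite(force))) stop("force must be finite")
  phase_series(force > threshold)
}

#' Threshold detector configuration
#'
#' @param thress_acc Acceleration-norm deviation threshold, m/s^2 (default 0.2).
#' @param thress_gyro Angular-rate norm threshold, rad/s (default 0.3).
#' @param g Gravity magnitude, m/s^2.
#' @return Object of class `threshold_config`.
#' @export
threshold_config <- function(thress_acc = 0.2, thress_gyro = 0.3, g = 9.81) {
  if (thress_acc <= 0 || thress_gyro <= 0) stop("thresholds must be positive")
  structure(list(thress_acc = thress_acc, thress_gyro = thress_gyro, g = g),
            class = "threshold_config")
}

#' Threshold-based ground-contact detection
#'
#' Labels sample j as ground contact iff both the deviation of the specific
#' force norm from gravity and the angular-rate norm are at or below their
#' thresholds: | ||acc_j|| - g | <= thress_acc and ||gyro_j|| <= thress_gyro.
#' Both quantities are small while the cane rests on the ground and large
#' while it swings.
#'
#' @param seq A calibrated [imu_sequence].
#' @param cfg A [threshold_config].
#' @return A [phase_series] of the same length as `seq`.
#' @export
detect_phase_threshold <- function(seq, cfg = threshold_config()) {
  stopifnot(inherits(cfg, "threshold_config"))
  acc_norm <- sqrt(rowSums(imu_acc(seq)^2))
  gyro_norm <- sqrt(rowSums(imu_gyro(seq)^2))
  phase_series(abs(acc_norm - cfg$g) <= cfg$thress_acc &
                 gyro_norm <= cfg$thress_gyro)
}

#' Detect cane gait events from the sagittal angular velocity
#'
#' During cane ambulation the sagittal (mediolateral-axis) angular velocity
#' shows one dominant positive peak per stride at cane mid-swing (MS),
#' flanked by negative peaks at cane take-off (end contact, EC) and landing
#' (initial contact, IC). MS peaks are found first (they are the largest);
#' EC is then the nearest preceding negative local minimum and IC the
#' nearest following one.
#'
#' @param sagittal_gyro Uniformly sampled angular velocity about the
#'   mediolateral axis, rad/s.
#' @param fs Sampling rate, Hz.
#' @param min_prominence Minimum prominence of an MS peak, rad/s.
#' @param min_separation Minimum separation between MS peaks, s; closer peaks
#'   are merged keeping the larger.
#' @return Object of class `event_set`: list with integer sample indices
#'   `ms`, `ic`, `ec`. A signal with no qualifying MS peak yields empty
#'   index vectors. An MS peak with no following (preceding) negative
#'   minimum in a truncated record keeps its MS index but contributes no IC
#'   (EC).
#' @export
detect_events <- function(sagittal_gyro, fs = 100,
                          min_prominence = 0.5, min_separation = 0.4) {
  x <- as.numeric(sagittal_gyro)
  if (!all(is.finite(x))) stop("sagittal gyro signal must be finite")
  empty <- structure(list(ms = integer(), ic = integer(), ec = integer()),
                     class = "event_set")
  if (length(x) < 3L) return(empty)
  pk <- pracma::findpeaks(x, minpeakheight = min_prominence,
                          minpeakdistance = max(1L, round(min_separation * fs)),
                          sortstr = TRUE)  # sorted so distance merging keeps the larger peak
  if (is.null(pk)) return(empty)
  if (is.null(dim(pk))) pk <- matrix(pk, nrow = 1)
  ms <- sort(pk[, 2])
  # candidate EC/IC: local minima with negative value, including record edges
  tr <- pracma::findpeaks(-x)
  mins <- if (is.null(tr)) integer() else {
    if (is.null(dim(tr))) tr <- matrix(tr, nrow = 1)
    sort(tr[tr[, 1] > 0, 2])
  }
  n <- length(x)
  if (x[1] < x[2] && x[1] < 0) mins <- c(1L, mins)
  if (x[n] < x[n - 1L] && x[n] < 0) mins <- c(mins, n)
  ec <- ic <- integer()
  for (m in ms) {
    before <- mins[mins < m]
    after <- mins[mins > m]
    if (length(before)) ec <- c(ec, before[length(before)])
    if (length(after)) ic <- c(ic, after[1])
  }
  ec <- unique(ec); ic <- unique(ic)
  # adjacent strides may share a single trough (assigned as both the IC of
  # one stride and the EC of the next); keep its IC role and enforce strict
  # EC/IC alternation so the event stream always maps to valid intervals
  ec <- setdiff(ec, ic)
  if (length(ec) && length(ic)) {
    ev <- rbind(data.frame(i = ic, type = "ic"),
                data.frame(i = ec, type = "ec"))
    ev <- ev[order(ev$i), ]
    keep <- c(TRUE, ev$type[-1] != ev$type[-nrow(ev)])
    ev <- ev[keep, ]
    ic <- ev$i[ev$type == "ic"]; ec <- ev$i[ev$type == "ec"]
  }
  structure(list(ms = as.integer(ms), ic = as.integer(ic),
                 ec = as.integer(ec)),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d MS, %d IC, %d EC events\n",
              length(x$ms), length(x$ic), length(x$ec)))
  invisible(x)
}

#' Convert gait events to a phase series
#'
#' Ground contact runs from each initial contact (IC) to the next end
#' contact (EC); no contact runs from each EC to the next IC. Samples before
#' the first IC/EC event take the label implied by that event (before an IC:
#' no contact; before an EC: contact). An empty event set yields all
#' no-contact.
#'
#' @param events An `event_set` from [detect_events].
#' @param n_samples Length of the output series.
#' @return A [phase_series] of length `n_samples`.
#' @export
events_to_phase <- function(events, n_samples) {
  stopifnot(inherits(events, "event_set"))
  ev <- rbind(
    if (length(events$ic)) data.frame(i = events$ic, contact_after = TRUE),
    if (length(events$ec)) data.frame(i = events$ec, contact_after = FALSE)
  )
  out <- rep(FALSE, n_samples)
  if (is.null(ev) || nrow(ev) == 0L) return(phase_series(out))
  if (any(ev$i < 1L | ev$i > n_samples)) stop("event index out of range")
  ev <- ev[order(ev$i), , drop = FALSE]
  if (any(duplicated(ev$i)) || any(diff(as.integer(ev$contact_after)) == 0))
    stop("overlapping contact intervals: consecutive events of the same type")
  state <- !ev$contact_after[1]  # label implied before the first event
  pos <- 1L
  for (k in seq_len(nrow(ev))) {
    if (ev$i[k] > pos) out[pos:(ev$i[k] - 1L)] <- state
    state <- ev$contact_after[k]
    pos <- ev$i[k]
  }
  out[pos:n_samples] <- state
  phase_series(out)
}

#' Voting-window configuration
#'
#' @param window Number of most recent raw labels in the causal majority
#'   vote (default 25).
#' @return Object of class `voting_config`.
#' @export
voting_config <- function(window = 25) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("voting window must be >= 1")
  structure(list(window = window), class = "voting_config")
}

#' Causal majority-vote smoothing of a phase series
#'
#' Label j becomes ground contact iff strictly more than half of the raw
#' labels in the causal window `[j - window + 1, j]` (truncated at the start
#' of the record) are ground contact. With the default 25-sample window any
#' contact burst shorter than 13 samples inside a long no-contact run (and
#' vice versa) is removed.
#'
#' @param raw A [phase_series].
#' @param cfg A [voting_config].
#' @return The smoothed [phase_series], same length as `raw`.
#' @export
voting_smooth <- function(raw, cfg = voting_config()) {
  stopifnot(inherits(cfg, "voting_config"))
  x <- as.integer(is_contact(raw))
  n <- length(x)
  w <- cfg$window
  cs <- cumsum(x)
  lo <- pmax(0L, seq_len(n) - w)          # exclusive lower cumsum index
  counts <- cs - c(0L, cs)[lo + 1L]
  sizes <- pmin(seq_len(n), w)
  phase_series(counts > sizes / 2)
}
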