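## Ground-truth activity labelling from treadmill speed.

## Vectorised threshold labelling; `eps` absorbs sensor noise around zero.
activity_from_speed <- function(speed_values, profile, eps = 0.05) {
  idx <- 1L + (abs(speed_values) >= eps) +
    (speed_values > profile$walk_upper) +
    (speed_values > profile$run_upper)
  factor(activity_levels()[idx], levels = activity_levels())
}

#' Zero-phase Butterworth smoothing of a speed stream
#'
#' Applies a low-pass Butterworth filter of the given order and cutoff
#' forward and backward (zero phase, so labels derived from the smoothed
#' trace are not lagged) to remove high-frequency noise before threshold
#' labelling.
#'
#' @param speed Speed stream tibble (`time_s`, `speed_mps`).
#' @param order Filter order (default 6).
#' @param cutoff_hz Cutoff frequency in Hz (default 50); must be below the
#'   Nyquist frequency of the stream.
#' @return A tibble on the same time grid with the smoothed `speed_mps`.
#' @export
smooth_speed <- function(speed, order = 6, cutoff_hz = 50) {
  fs <- 1 / median(diff(speed$time_s))
  if (cutoff_hz >= fs / 2) {
    abort(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                  cutoff_hz, fs / 2))
  }
  filt <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  x <- speed$speed_mps
  n <- length(x)
  # odd-reflection padding absorbs the forward/backward filter transients so
  # the ends of the trace are not distorted
  np <- min(n - 1L, 30L * order)
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- as.numeric(signal::filtfilt(filt, xp))[(np + 1):(np + n)]
  tibble::tibble(time_s = speed$time_s, speed_mps = y)
}

#' Label a speed stream with activities via per-subject thresholds
#'
#' Speeds within `stand_eps` of zero are standing; `(0, walk_upper]` is
#' walking, `(walk_upper, run_upper]` running (upper bounds inclusive), and
#' anything above `run_upper` sprinting.
#'
#' @param speed Speed stream tibble (`time_s`, `speed_mps`), usually after
#'   [smooth_speed()].
#' @param profile A [subject_profile()] providing the thresholds.
#' @param stand_eps Speed magnitude (m/s) below which the subject counts as
#'   standing; noisy or filtered speed never equals exactly zero.
#' @return A tibble with columns `time_s`, `label` (factor over
#'   [activity_levels()]).
#' @export
label_by_speed <- function(speed, profile, stand_eps = 0.05) {
  if (any(speed$speed_mps < -stand_eps)) {
    abort("speeds must be non-negative (beyond the stand tolerance)")
  }
  tibble::tibble(
    time_s = speed$time_s,
    label = activity_from_speed(speed$speed_mps, profile, stand_eps)
  )
}

#' Ground-truth label series for a session
#'
#' Convenience wrapper: smooths the session's treadmill-speed channel with
#' the configured zero-phase Butterworth filter, then thresholds it with the
#' session's subject profile.
#'
#' @param session A `gait_session` from [generate_session()].
#' @return A label series tibble (`time_s`, `label`).
#' @export
session_labels <- function(session) {
  cfg <- session$config
  sp <- session_channel_data(session, "treadmill_speed")
  sm <- smooth_speed(sp, order = cfg$label_filter_order,
                     cutoff_hz = cfg$label_filter_cutoff_hz)
  label_by_speed(sm, session$profile, stand_eps = cfg$stand_eps)
}

#' Majority label of a window
#'
#' Assigns to the window `[start, start + len)` the majority label of the
#' samples it contains; an exact tie is broken toward the label of the sample
#' closest to the window center.
#'
#' @param labels Label series tibble (`time_s`, `label`).
#' @param window_start Window start time in seconds.
#' @param window_len Window length in seconds.
#' @return A single activity label (factor).
#' @export
window_label <- function(labels, window_start, window_len) {
  # tolerant half-open bounds: window starts are step multiples and may carry
  # binary rounding error relative to the sample grid
  sel <- labels$time_s >= window_start - 1e-9 &
    labels$time_s < window_start + window_len - 1e-9
  if (!any(sel)) abort("window contains no label samples")
  lab <- labels$label[sel]
  counts <- table(lab)
  top <- counts[counts == max(counts)]
  if (length(top) == 1L) {
    return(factor(names(top), levels = levels(labels$label)))
  }
  t_sel <- labels$time_s[sel]
  center <- lab[which.min(abs(t_sel - (window_start + window_len / 2)))]
  center
}

## Vectorised window labelling on a uniform label grid (same majority /
## center-tie rule as window_label, used by extract_features).
window_labels_uniform <- function(labels, starts, window_len) {
  fs <- 1 / median(diff(labels$time_s))
  wlen <- round(window_len * fs)
  idx <- window_index(fs, starts, window_len)
  lab_int <- matrix(as.integer(labels$label)[idx], nrow = wlen)
  nlev <- nlevels(labels$label)
  counts <- vapply(seq_len(nlev), function(k) colSums(lab_int == k),
                   numeric(ncol(lab_int)))
  counts <- matrix(counts, ncol = nlev)
  best <- max.col(counts, ties.method = "first")
  maxc <- counts[cbind(seq_len(nrow(counts)), best)]
  tied <- rowSums(counts == maxc) > 1L
  if (any(tied)) {
    center_row <- min(wlen, floor(wlen / 2) + 1L)
    best[tied] <- lab_int[center_row, tied]
  }
  factor(levels(labels$label)[best], levels = levels(labels$label))
}
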