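## Windowed feature extraction: the 44-feature representation
## (ACC, FPM, FPSD, MF, H1-H3) on 0.5 s windows with 0.30 s overlap.

META_COLS <- c("subject_id", "trial_id", "window_start_s", "label",
               "speed_mean_mps", "fp_diff_mean_n")

#' Sliding-window start times
#'
#' Windows of length `window` advance by `window - overlap` (default
#' 0.5 - 0.30 = 0.2 s); the trailing partial window is dropped, so a 150 s
#' record yields `floor((150 - 0.5)/0.2) + 1 = 748` windows.
#'
#' @param duration Record duration in seconds.
#' @param window Window length in seconds.
#' @param overlap Overlap between consecutive windows in seconds; must be
#'   smaller than `window`.
#' @return Numeric vector of window start times (possibly empty).
#' @examples
#' length(sliding_windows(150))
#' @export
sliding_windows <- function(duration, window = 0.5, overlap = 0.30) {
  stopifnot_scalar_number(duration, "duration")
  stopifnot_scalar_number(window, "window")
  stopifnot_scalar_number(overlap, "overlap")
  if (overlap >= window) abort("`overlap` must be smaller than `window`")
  if (overlap < 0 || window <= 0) abort("window and overlap must be non-negative")
  if (window > duration) return(numeric(0))
  step <- window - overlap
  n <- floor_tol((duration - window) / step) + 1
  (seq_len(n) - 1) * step
}

#' Mean vector magnitude of a tri-axial accelerometer window
#'
#' @param xyz Matrix or data frame with three columns (x, y, z samples).
#' @return Mean over samples of the per-sample Euclidean norm.
#' @examples
#' acc_feature(cbind(3, 4, 0))
#' @export
acc_feature <- function(xyz) {
  m <- as.matrix(xyz)
  if (nrow(m) == 0L) abort("empty window")
  mean(sqrt(rowSums(m^2)))
}

#' Force-plate window features: mean and standard deviation
#'
#' @param x Numeric vector of vertical force samples in one window.
#' @return Named vector `c(mean, sd)`; a single-sample window has SD 0 by
#'   convention.
#' @export
fp_features <- function(x) {
  if (length(x) == 0L) abort("empty window")
  c(mean = mean(x), sd = if (length(x) < 2L) 0 else sd(x))
}

#' Median frequency of a signal window
#'
#' The frequency at which the cumulative one-sided power spectral density
#' (single Hann-windowed periodogram) reaches half the total power, with
#' linear interpolation between spectral bins. An all-zero window returns
#' 0 Hz by convention.
#'
#' @param x Numeric window samples (length at least 2).
#' @param fs Sampling rate in Hz.
#' @return Median frequency in Hz.
#' @export
median_frequency <- function(x, fs) {
  if (length(x) < 2L) abort("window must have at least 2 samples")
  if (all(x == 0)) return(0)
  mf_windows(matrix(x, ncol = 1), fs)
}

## Vectorised median frequency over the columns of a window matrix.
mf_windows <- function(xmat, fs) {
  n <- nrow(xmat)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))  # Hann
  sp <- mvfft(xmat * w)
  nk <- floor(n / 2) + 1L
  p <- Mod(sp[seq_len(nk), , drop = FALSE])^2
  freqs <- (seq_len(nk) - 1) * fs / n
  cs <- apply(p, 2L, cumsum)
  cs <- matrix(cs, nrow = nk)
  total <- cs[nk, ]
  out <- numeric(ncol(xmat))
  zero <- total <= 0
  half <- total / 2
  k <- colSums(cs < rep(half, each = nk)) + 1L
  for (j in which(!zero)) {
    kj <- k[j]
    prev_c <- if (kj == 1L) 0 else cs[kj - 1L, j]
    prev_f <- if (kj == 1L) 0 else freqs[kj - 1L]
    seg <- cs[kj, j] - prev_c
    out[j] <- prev_f + (half[j] - prev_c) / seg * (freqs[kj] - prev_f)
  }
  out[zero] <- 0
  if (ncol(xmat) == 1L) out[1] else out
}

#' Amplitude-histogram features of an sEMG window
#'
#' Fractions of samples whose absolute deviation from the window mean lies
#' within 0–1 SD (H1), 1–2 SD (H2), and beyond 2 SD (H3) of the window's own
#' sample SD. The three fractions sum to one; a zero-SD window is `(1, 0, 0)`
#' by convention.
#'
#' @param x Numeric window samples.
#' @return Named vector `c(H1, H2, H3)`.
#' @examples
#' histogram_bins(c(-1, 1))
#' @export
histogram_bins <- function(x) {
  if (length(x) == 0L) abort("empty window")
  s <- if (length(x) < 2L) 0 else sd(x)
  if (s == 0) return(c(H1 = 1, H2 = 0, H3 = 0))
  z <- abs(x - mean(x)) / s
  c(H1 = mean(z <= 1), H2 = mean(z > 1 & z <= 2), H3 = mean(z > 2))
}

## Index matrix mapping each window to its sample rows on a uniform grid
## sampled at `fs`; window starts are multiples of the step so windows are
## exactly window*fs samples long. Half-open on the right.
window_index <- function(fs, starts, window) {
  wlen <- round(window * fs)
  i0 <- round(starts * fs)
  outer(seq_len(wlen), i0, `+`)
}

#' Canonical feature specification for a channel set
#'
#' One ACC feature per accelerometer channel, FPM and FPSD per force plate,
#' and MF plus H1/H2/H3 per sEMG channel — 44 features for the full-session
#' layout. Column order is fixed: ACC, FPM, FPSD, MF, then H1–H3 grouped by
#' sEMG channel.
#'
#' @param channels Channel spec tibble (e.g. [session_channels()] or a
#'   session's `channels`).
#' @return A tibble with columns `feature_id`, `family`, `channel_id`.
#' @export
canonical_feature_spec <- function(channels = session_channels()) {
  accel <- dplyr::filter(channels, .data$modality == "accel")
  plates <- dplyr::filter(channels, .data$modality == "force_plate")
  semg <- dplyr::filter(channels, .data$modality == "semg")
  strip <- function(id, prefix) sub(paste0("^", prefix, "_"), "", id)
  rows <- list(
    tibble::tibble(feature_id = paste0("acc_", strip(accel$channel_id, "accel")),
                   family = "ACC", channel_id = accel$channel_id),
    tibble::tibble(feature_id = paste0("fpm_", plates$side),
                   family = "FPM", channel_id = plates$channel_id),
    tibble::tibble(feature_id = paste0("fpsd_", plates$side),
                   family = "FPSD", channel_id = plates$channel_id),
    tibble::tibble(feature_id = paste0("mf_", strip(semg$channel_id, "semg")),
                   family = "MF", channel_id = semg$channel_id)
  )
  hbins <- tidyr::crossing(channel_id = semg$channel_id,
                           family = c("H1", "H2", "H3"))
  hbins <- dplyr::arrange(hbins, match(.data$channel_id, semg$channel_id),
                          .data$family)
  hbins$feature_id <- paste0(tolower(hbins$family), "_",
                             strip(hbins$channel_id, "semg"))
  dplyr::bind_rows(c(rows, list(hbins)))[, c("feature_id", "family", "channel_id")]
}

#' Extract the windowed feature matrix of a session
#'
#' Slides 0.5 s windows (0.30 s overlap by default, configurable through the
#' session config) over all channels named in the feature spec and computes
#' each feature from the samples of its source channel falling in
#' `[start, start + window)`. Windows are labelled with the majority activity
#' of the smoothed-speed label series. Streams keep their native rates; no
#' resampling is performed.
#'
#' @param session A `gait_session`.
#' @param spec Feature spec tibble (default: the canonical full-session
#'   spec); use [case_feature_spec()] for ablation subsets.
#' @param labels Optional label series; defaults to [session_labels()].
#' @param include_references Add `speed_mean_mps` and `fp_diff_mean_n`
#'   per-window reference columns used by the principal-component
#'   diagnostics.
#' @return A tibble with metadata columns (`subject_id`, `trial_id`,
#'   `window_start_s`, `label`, references) followed by one column per
#'   feature, in spec order.
#' @export
extract_features <- function(session, spec = NULL, labels = NULL,
                             include_references = TRUE) {
  cfg <- session$config
  if (is.null(spec)) spec <- canonical_feature_spec(session$channels)
  missing_ch <- setdiff(spec$channel_id, session$channels$channel_id)
  if (length(missing_ch) > 0) {
    abort(paste0("feature spec names channel(s) absent from the session: ",
                 paste(missing_ch, collapse = ", ")))
  }
  starts <- sliding_windows(session$duration_s, cfg$window_s, cfg$overlap_s)
  if (length(starts) == 0L) abort("record too short for a single window")
  if (is.null(labels)) labels <- session_labels(session)
  win_lab <- window_labels_uniform(labels, starts, cfg$window_s)

  out <- tibble::tibble(
    subject_id = session$subject_id,
    trial_id = session$trial_id,
    window_start_s = starts,
    label = win_lab
  )
  if (include_references) {
    sp <- session_channel_data(session, "treadmill_speed")
    idx <- window_index(cfg$fs_speed, starts, cfg$window_s)
    out$speed_mean_mps <- colMeans(matrix(sp$speed_mps[idx], ncol = length(starts)))
    fl <- session_channel_data(session, "force_plate_left")$value
    fr <- session_channel_data(session, "force_plate_right")$value
    idxf <- window_index(cfg$fs_force, starts, cfg$window_s)
    out$fp_diff_mean_n <-
      colMeans(matrix(fl[idxf], ncol = length(starts))) -
      colMeans(matrix(fr[idxf], ncol = length(starts)))
  }

  vals <- matrix(NA_real_, nrow = length(starts), ncol = nrow(spec),
                 dimnames = list(NULL, spec$feature_id))
  for (ch in unique(spec$channel_id)) {
    ch_i <- match(ch, session$channels$channel_id)
    stream <- session$channels$data[[ch_i]]
    fs <- session$channels$sampling_rate[ch_i]
    fams <- spec$family[spec$channel_id == ch]
    idx <- window_index(fs, starts, cfg$window_s)
    if ("ACC" %in% fams) {
      nrm <- sqrt(stream$x^2 + stream$y^2 + stream$z^2)
      vals[, spec$feature_id[spec$channel_id == ch & spec$family == "ACC"]] <-
        colMeans(matrix(nrm[idx], ncol = length(starts)))
    }
    if (any(c("FPM", "FPSD") %in% fams)) {
      m <- matrix(stream$value[idx], ncol = length(starts))
      if ("FPM" %in% fams) {
        vals[, spec$feature_id[spec$channel_id == ch & spec$family == "FPM"]] <-
          colMeans(m)
      }
      if ("FPSD" %in% fams) {
        vals[, spec$feature_id[spec$channel_id == ch & spec$family == "FPSD"]] <-
          col_sds(m)
      }
    }
    if (any(c("MF", "H1", "H2", "H3") %in% fams)) {
      m <- matrix(stream$value[idx], ncol = length(starts))
      if ("MF" %in% fams) {
        vals[, spec$feature_id[spec$channel_id == ch & spec$family == "MF"]] <-
          mf_windows(m, fs)
      }
      if (any(c("H1", "H2", "H3") %in% fams)) {
        n <- nrow(m)
        mu <- colMeans(m)
        s <- col_sds(m)
        z <- abs(m - rep(mu, each = n)) / rep(pmax(s, .Machine$double.eps), each = n)
        h1 <- colMeans(z <= 1)
        h2 <- colMeans(z > 1 & z <= 2)
        h3 <- colMeans(z > 2)
        degenerate <- s == 0
        h1[degenerate] <- 1; h2[degenerate] <- 0; h3[degenerate] <- 0
        put <- function(fam, v) {
          ids <- spec$feature_id[spec$channel_id == ch & spec$family == fam]
          if (length(ids) > 0) vals[, ids] <<- v
        }
        put("H1", h1); put("H2", h2); put("H3", h3)
      }
    }
  }
  dplyr::bind_cols(out, tibble::as_tibble(vals))
}

#' Extract features for every session in a study
#'
#' @param study A `gait_study` (or list of sessions).
#' @param ... Passed to [extract_features()].
#' @return One tibble with all sessions' windows stacked.
#' @export
study_features <- function(study, ...) {
  dplyr::bind_rows(lapply(study, extract_features, ...))
}

#' Names of the feature columns of a feature matrix
#' @param fm A feature matrix tibble from [extract_features()].
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(fm) setdiff(names(fm), META_COLS)

#' Fit a z-score normalizer on a (training) feature matrix
#'
#' Learns per-feature mean and SD. Normalization statistics are fit on
#' training folds only and applied unchanged to test data, so test windows
#' never leak into the scaling.
#'
#' @param fm Feature matrix tibble (at least two rows).
#' @return A `feature_normalizer`.
#' @export
fit_normalizer <- function(fm) {
  cols <- feature_cols(fm)
  if (nrow(fm) < 2L) abort("need at least 2 rows to fit a normalizer")
  m <- as.matrix(fm[cols])
  mu <- colMeans(m)
  s <- col_sds(m)
  if (any(s == 0)) {
    abort(paste0("zero-variance feature(s): ",
                 paste(cols[s == 0], collapse = ", ")))
  }
  structure(list(feature = cols, mean = mu, sd = s),
            class = "feature_normalizer")
}

#' Apply a fitted normalizer to a feature matrix
#'
#' @param fm Feature matrix tibble.
#' @param normalizer A `feature_normalizer` from [fit_normalizer()].
#' @return `fm` with feature columns replaced by `(x - mean) / sd` using the
#'   normalizer's (training) statistics.
#' @export
apply_normalizer <- function(fm, normalizer) {
  cols <- feature_cols(fm)
  if (!setequal(cols, normalizer$feature)) {
    abort("feature columns do not match the normalizer")
  }
  m <- as.matrix(fm[normalizer$feature])
  m <- sweep(sweep(m, 2L, normalizer$mean), 2L, normalizer$sd, `/`)
  fm[normalizer$feature] <- tibble::as_tibble(m)
  fm
}

#' @export
print.feature_normalizer <- function(x, ...) {
  cat(sprintf("<feature_normalizer> %d features\n", length(x$feature)))
  invisible(x)
}
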