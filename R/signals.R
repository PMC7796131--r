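## Synthetic multimodal gait signal generators.
##
## All generators are deterministic given their seed, vectorised over the
## whole trial, and share a common kinematic backbone: the belt-speed trace
## (first-order lag toward the commanded activity's preferred speed) and a
## stride-phase integral derived from it.

time_grid <- function(duration, fs) {
  n <- round(duration * fs)
  (seq_len(n) - 1) / fs
}

## Stride frequency as a function of instantaneous speed; frozen while the
## subject is standing so force/gait phase does not advance.
stride_phase <- function(speed, fs, profile, config) {
  f <- (profile$stride_frequency_base + config$stride_speed_slope * speed) *
    (speed > config$stand_eps)
  cumsum(f) / fs
}

interp_speed <- function(speed, times) {
  approx(speed$time_s, speed$speed_mps, xout = times, rule = 2)$y
}

## Centered moving average (cumsum-based, O(n)) that falls back to the raw
## value near the edges; softens per-sample activity-gain steps in the sEMG
## model.
smooth_steps <- function(x, fs, width_s = 0.25) {
  k <- max(1L, round(width_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  if (k <= 1L || n < k) return(x)
  h <- (k - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  y <- x
  core <- (h + 1L):(n - h)
  y[core] <- (cs[core + h + 1L] - cs[core - h]) / k
  y
}

#' Simulate a self-paced treadmill speed stream
#'
#' The subject's speed follows each commanded activity's preferred speed with
#' a first-order lag (time constant = the profile's `response_lag`), plus
#' additive zero-mean Gaussian noise, clamped at zero. The trace starts at the
#' first command's preferred speed.
#'
#' @param schedule Command schedule tibble from [generate_schedule()].
#' @param profile A [subject_profile()].
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed for the noise.
#' @param noise_sd Noise standard deviation in m/s.
#' @return A tibble with columns `time_s`, `speed_mps`.
#' @examples
#' sch <- generate_schedule(seed = 1, n_commands = 3)
#' sp <- simulate_speed(sch, subject_profile("s1", 1.3, 2.4), fs = 100)
#' @export
simulate_speed <- function(schedule, profile, fs = 300, seed = 1,
                           noise_sd = 0.05) {
  stopifnot_scalar_number(fs, "fs")
  if (fs <= 0) abort("`fs` must be positive")
  duration <- schedule_duration(schedule)
  t <- time_grid(duration, fs)
  act <- schedule_activity_at(schedule, t)
  target <- profile$preferred_speeds[as.character(act)]
  alpha <- 1 - exp(-1 / (fs * profile$response_lag))
  v <- stats::filter(alpha * target, 1 - alpha, method = "recursive",
                     init = target[1])
  set.seed(seed)
  v <- as.numeric(v) + stats::rnorm(length(t), 0, noise_sd)
  tibble::tibble(time_s = t, speed_mps = pmax(v, 0))
}

band_limited_noise <- function(n, fs, lo, hi, seed) {
  set.seed(seed)
  x <- stats::rnorm(n)
  hi <- min(hi, 0.45 * fs)
  filt <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  y <- as.numeric(signal::filter(filt, x))
  y / max(sd(y), .Machine$double.eps)
}

#' Synthesize a surface-EMG channel
#'
#' A surrogate sEMG model: a band-limited (20–450 Hz) zero-mean Gaussian
#' carrier, amplitude-modulated by a stride-cycle envelope and scaled to an
#' activity-dependent RMS (the configured per-segment gains). Median
#' frequency shifts with activity through the mixing weight of a
#' high-frequency carrier band. This reproduces the feature-level contrasts
#' the downstream analysis uses, not muscle physiology.
#'
#' @param speed Speed stream from [simulate_speed()].
#' @param spec One-row channel spec with `modality == "semg"`.
#' @param profile A [subject_profile()].
#' @param seed Integer seed.
#' @param config A [session_config()].
#' @return A tibble with columns `time_s`, `value` (mV).
#' @export
synthesize_semg <- function(speed, spec, profile, seed = 1,
                            config = session_config()) {
  if (spec$modality != "semg") abort("`spec` must be an sEMG channel")
  fs <- spec$sampling_rate
  duration <- max(speed$time_s) + speed$time_s[2] - speed$time_s[1]
  t <- time_grid(duration, fs)
  v <- interp_speed(speed, t)
  act <- as.character(activity_from_speed(v, profile, config$stand_eps))

  gains <- config$semg_gains[[spec$segment]]
  g <- smooth_steps(unname(gains[act]), fs)
  w <- smooth_steps(unname(config$semg_mf_weight[act]), fs)

  lo_band <- band_limited_noise(t_len <- length(t), fs,
                                config$semg_band[1], config$semg_band_split,
                                sub_seed(seed, 1))
  hi_band <- band_limited_noise(t_len, fs,
                                config$semg_band_split, config$semg_band[2],
                                sub_seed(seed, 2))
  carrier <- (lo_band + w * hi_band) / sqrt(1 + w^2)

  phase <- stride_phase(v, fs, profile, config)
  depth <- config$semg_env_depth * pmin(v / 0.5, 1)
  offset <- if (spec$side == "left") 0 else pi
  env <- 1 + depth * cos(2 * pi * phase + offset)
  # keep the configured gain equal to the realised RMS despite the envelope
  g <- g / sqrt(1 + depth^2 / 2)

  tibble::tibble(time_s = t, value = g * env * carrier)
}

#' Synthesize a tri-axial accelerometer channel
#'
#' Constant 1 g gravity on the z axis plus stride-frequency harmonics whose
#' amplitude grows linearly with speed, with a larger gain for shank-mounted
#' than thigh-mounted units (distal points on the leg experience larger
#' accelerations), plus additive Gaussian noise.
#'
#' @inheritParams synthesize_semg
#' @param spec One-row channel spec with `modality == "accel"`.
#' @return A tibble with columns `time_s`, `x`, `y`, `z` (units of g).
#' @export
synthesize_accelerometer <- function(speed, spec, profile, seed = 1,
                                     config = session_config()) {
  if (spec$modality != "accel") abort("`spec` must be an accelerometer channel")
  fs <- spec$sampling_rate
  duration <- max(speed$time_s) + speed$time_s[2] - speed$time_s[1]
  t <- time_grid(duration, fs)
  v <- interp_speed(speed, t)
  phase <- stride_phase(v, fs, profile, config)
  amp <- config$accel_amp_per_speed[[spec$segment]] * v

  set.seed(sub_seed(seed, 3))
  # harmonic phases are fixed (not random) so left/right channels of a unit
  # stay exactly anti-phase; stance-side coherence across channels is what
  # lets the left-right contrast form its own variance direction downstream
  offset <- if (spec$side == "left") 0 else pi
  a1 <- 2 * pi * phase + offset
  x <- amp * (0.8 * sin(a1 + 0.4) + 0.3 * sin(2 * a1))
  y <- amp * 0.5 * sin(a1 + 1.2)
  # dominant vertical harmonic peaks mid-stance (impact loading), keeping the
  # windowed magnitude coherent with the ipsilateral plate's force bump
  z <- 1 + amp * (0.9 * sin(a1 + pi + 0.5) + 0.3 * sin(2 * a1 + 2.1))
  n <- length(t)
  x <- x + stats::rnorm(n, 0, config$accel_noise_sd)
  y <- y + stats::rnorm(n, 0, config$accel_noise_sd)
  z <- z + stats::rnorm(n, 0, config$accel_noise_sd)
  tibble::tibble(time_s = t, x = x, y = y, z = z)
}

## Single-support vertical GRF stance shapes on normalised stance phase
## v in [0, 1]: walking is double-peaked, running single-peaked.
walk_shape <- function(v) sin(pi * v) * (1 + 0.4 * cos(2 * pi * v))
run_shape <- function(v) sin(pi * v)
walk_shape_mean <- 2 / pi - 0.8 / (3 * pi)
run_shape_mean <- 2 / pi

#' Synthesize left/right vertical force-plate streams
#'
#' Standing splits body weight evenly across the plates with low-amplitude
#' sway; walking produces left/right alternating double-peaked stance
#' profiles with double-support overlap (both plates loaded); running and
#' sprinting produce single-peaked profiles with higher peaks and flight
#' intervals (both plates zero). Stance peaks are scaled so the cycle-mean
#' total force equals body weight. Forces are non-negative. A configurable
#' fraction of strides can have their left/right assignment swapped to
#' emulate cross-plate strikes.
#'
#' @inheritParams synthesize_semg
#' @return A tibble with columns `time_s`, `left_n`, `right_n` (newtons).
#' @export
synthesize_force_plates <- function(speed, profile, seed = 1,
                                    config = session_config()) {
  fs <- config$fs_force
  duration <- max(speed$time_s) + speed$time_s[2] - speed$time_s[1]
  t <- time_grid(duration, fs)
  v <- interp_speed(speed, t)
  act <- as.character(activity_from_speed(v, profile, config$stand_eps))
  weight <- config$body_mass_kg * 9.81
  n <- length(t)

  phase <- stride_phase(v, fs, profile, config)
  u_left <- phase %% 1
  u_right <- (phase + 0.5) %% 1

  duty <- c(stand = NA_real_, walk = config$walk_duty,
            run = config$run_duty, sprint = config$sprint_duty)[act]
  walking <- act == "walk"
  moving <- act != "stand"

  leg_force <- function(u) {
    f <- numeric(n)
    in_stance <- moving & u < duty
    vphase <- u[in_stance] / duty[in_stance]
    w <- walking[in_stance]
    peak <- ifelse(w,
                   weight / (2 * duty[in_stance] * walk_shape_mean),
                   weight / (2 * duty[in_stance] * run_shape_mean))
    shape <- ifelse(w, walk_shape(vphase), run_shape(vphase))
    f[in_stance] <- peak * shape
    f
  }
  left <- leg_force(u_left)
  right <- leg_force(u_right)

  set.seed(sub_seed(seed, 4))
  # standing: even weight split plus slow mediolateral sway
  standing <- !moving
  sway <- config$fp_sway_sd *
    (sqrt(2) * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi)) +
       0.3 * stats::rnorm(n))
  left[standing] <- weight / 2 + sway[standing]
  right[standing] <- weight / 2 - sway[standing]

  # stance noise only where a plate is loaded, so flight stays exactly zero
  left <- left + stats::rnorm(n, 0, config$fp_noise_sd) * (left > 0)
  right <- right + stats::rnorm(n, 0, config$fp_noise_sd) * (right > 0)
  left <- pmax(left, 0)
  right <- pmax(right, 0)

  if (config$cross_strike_fraction > 0) {
    stride <- floor(phase)
    ids <- unique(stride)
    swap_stride <- ids[stats::runif(length(ids)) < config$cross_strike_fraction]
    swap <- stride %in% swap_stride
    tmp <- left[swap]
    left[swap] <- right[swap]
    right[swap] <- tmp
  }
  tibble::tibble(time_s = t, left_n = left, right_n = right)
}
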