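#' Session generator configuration
#'
#' All tunable knobs of the synthetic-session generator with their default
#' values. Defaults define the study conditions the package emulates: 150 s
#' trials of commanded stand/walk/run/sprint on a self-paced split-belt
#' treadmill instrumented with 8 combined sEMG/accelerometer units, two
#' force plates and a belt-speed log. Pass overrides as named arguments.
#'
#' Key groups:
#' \describe{
#'   \item{sampling}{`fs_semg` (1000 Hz), `fs_accel` (100 Hz), `fs_force`
#'     (1000 Hz), `fs_speed` (300 Hz; above twice the 50 Hz labelling filter
#'     cutoff).}
#'   \item{speed}{`speed_noise_sd` (m/s) additive Gaussian noise on the
#'     lag-filtered belt speed.}
#'   \item{gait}{`stride_speed_slope` (Hz per m/s) added to the profile's
#'     stride-frequency base; `walk_duty`/`run_duty`/`sprint_duty` stance
#'     duty factors (walking > 0.5 gives double support, running < 0.5
#'     gives flight phases).}
#'   \item{sEMG}{`semg_gains`: per-segment, per-activity RMS amplitude (mV).
#'     The walk-to-run contrast is deliberately larger for shank than thigh
#'     muscles — distal muscles change their activation profile more between
#'     gaits; `semg_mf_weight`: per-activity weight of the high-frequency
#'     carrier band, shifting median frequency with activity;
#'     `semg_env_depth`: stride-cycle amplitude modulation depth;
#'     `semg_band`/`semg_band_split`: carrier band edges in Hz.}
#'   \item{accelerometer}{`accel_amp_per_speed`: harmonic amplitude in g per
#'     m/s, larger for shank than thigh (distal points see larger
#'     accelerations); `accel_noise_sd` (g).}
#'   \item{force plates}{`body_mass_kg`, `fp_sway_sd` (N, standing sway),
#'     `fp_noise_sd` (N, stance noise), `cross_strike_fraction` (fraction of
#'     strides whose left/right plate assignment is swapped).}
#'   \item{labelling}{`stand_eps` (m/s) below which speed counts as
#'     standing; `label_filter_order`, `label_filter_cutoff_hz` for the
#'     zero-phase Butterworth speed smoother.}
#'   \item{windows}{`window_s` (0.5), `overlap_s` (0.30).}
#' }
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `session_config`.
#' @examples
#' cfg <- session_config(cross_strike_fraction = 0.1)
#' cfg$fs_semg
#' @export
session_config <- function(...) {
  defaults <- list(
    fs_semg = 1000,
    fs_accel = 100,
    fs_force = 1000,
    fs_speed = 300,
    speed_noise_sd = 0.05,
    stride_speed_slope = 0.18,
    walk_duty = 0.60,
    run_duty = 0.35,
    sprint_duty = 0.30,
    semg_band = c(20, 450),
    semg_band_split = 150,
    semg_env_depth = 0.5,
    semg_gains = list(
      shank = c(stand = 0.02, walk = 0.08, run = 0.22, sprint = 0.30),
      thigh = c(stand = 0.02, walk = 0.10, run = 0.13, sprint = 0.15)
    ),
    semg_mf_weight = c(stand = 0.4, walk = 0.6, run = 1.0, sprint = 1.3),
    accel_amp_per_speed = c(shank = 0.28, thigh = 0.10),
    accel_noise_sd = 0.02,
    body_mass_kg = 70,
    fp_sway_sd = 15,
    fp_noise_sd = 8,
    cross_strike_fraction = 0,
    stand_eps = 0.05,
    label_filter_order = 6,
    label_filter_cutoff_hz = 50,
    window_s = 0.5,
    overlap_s = 0.30
  )
  dots <- list(...)
  if (length(dots) > 0) {
    bad <- setdiff(names(dots), names(defaults))
    if (length(bad) > 0 || is.null(names(dots)) || any(names(dots) == "")) {
      abort(paste0("unknown session_config option(s): ",
                   paste(bad, collapse = ", ")))
    }
    defaults[names(dots)] <- dots
  }
  structure(defaults, class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat(sprintf("  rates: sEMG %g Hz, accel %g Hz, force %g Hz, speed %g Hz\n",
              x$fs_semg, x$fs_accel, x$fs_force, x$fs_speed))
  cat(sprintf("  window %.2f s / overlap %.2f s; body mass %g kg\n",
              x$window_s, x$overlap_s, x$body_mass_kg))
  invisible(x)
}
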