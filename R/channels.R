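#' Construct a channel specification
#'
#' @param channel_id Unique channel label.
#' @param modality One of `"semg"`, `"accel"`, `"force_plate"`, `"speed"`.
#' @param muscle Muscle site for sEMG/accelerometer channels, `"none"`
#'   otherwise.
#' @param segment `"shank"`, `"thigh"` or `"none"`.
#' @param side `"left"`, `"right"` or `"none"`.
#' @param sampling_rate Sampling rate in Hz.
#' @return A one-row tibble.
#' @export
channel_spec <- function(channel_id, modality, muscle = "none",
                         segment = "none", side = "none", sampling_rate) {
  modality <- match.arg(modality, c("semg", "accel", "force_plate", "speed"))
  muscle <- match.arg(muscle, c("gastrocnemius", "tibialis_anterior",
                                "hamstring", "vastus_medialis", "none"))
  segment <- match.arg(segment, c("shank", "thigh", "none"))
  side <- match.arg(side, c("left", "right", "none"))
  if (modality %in% c("semg", "accel") && (muscle == "none" || segment == "none")) {
    abort("sEMG and accelerometer channels need a muscle and a segment")
  }
  stopifnot_scalar_number(sampling_rate, "sampling_rate")
  tibble::tibble(
    channel_id = channel_id, modality = modality, muscle = muscle,
    segment = segment, side = side, sampling_rate = sampling_rate
  )
}

## The 8 wearable units: two shank muscles and two thigh muscles per leg.
unit_layout <- function() {
  tibble::tibble(
    muscle = rep(c("gastrocnemius", "tibialis_anterior",
                   "hamstring", "vastus_medialis"), each = 2),
    segment = rep(c("shank", "shank", "thigh", "thigh"), each = 2),
    side = rep(c("left", "right"), times = 4)
  )
}

#' Full-session channel layout
#'
#' The 19 channels of a complete session: 8 sEMG and 8 tri-axial
#' accelerometer channels (one of each per wearable unit on gastrocnemius,
#' tibialis anterior, hamstring and vastus medialis, both legs), two vertical
#' force-plate channels, and one treadmill-speed channel.
#'
#' @param config A [session_config()] (provides the sampling rates).
#' @return A tibble of channel specs (one row per channel).
#' @export
session_channels <- function(config = session_config()) {
  units <- unit_layout()
  semg <- dplyr::mutate(
    units,
    channel_id = paste("semg", .data$muscle, .data$side, sep = "_"),
    modality = "semg", sampling_rate = config$fs_semg
  )
  accel <- dplyr::mutate(
    units,
    channel_id = paste("accel", .data$muscle, .data$side, sep = "_"),
    modality = "accel", sampling_rate = config$fs_accel
  )
  plates <- tibble::tibble(
    muscle = "none", segment = "none", side = c("left", "right"),
    channel_id = c("force_plate_left", "force_plate_right"),
    modality = "force_plate", sampling_rate = config$fs_force
  )
  speed <- tibble::tibble(
    muscle = "none", segment = "none", side = "none",
    channel_id = "treadmill_speed", modality = "speed",
    sampling_rate = config$fs_speed
  )
  dplyr::select(
    dplyr::bind_rows(semg, accel, plates, speed),
    "channel_id", "modality", "muscle", "segment", "side", "sampling_rate"
  )
}
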