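#' Generate one synthetic recording session (trial)
#'
#' Composes the command schedule, the self-paced speed trace and all 19
#' channels (8 sEMG, 8 tri-axial accelerometers, 2 force plates, treadmill
#' speed) into a `gait_session`. Deterministic given `seed`: the session seed
#' fans out to independent per-channel sub-seeds, so each channel is also
#' individually reproducible.
#'
#' @param profile A [subject_profile()].
#' @param trial_id Trial number within the subject's session set.
#' @param config A [session_config()].
#' @param seed Integer seed.
#' @param schedule Optional pre-built command schedule; by default one is
#'   generated from a seed derived from `seed`.
#' @return A `gait_session`: list with `subject_id`, `trial_id`, `profile`,
#'   `schedule`, `config`, `seed`, `duration_s` and a `channels` tibble whose
#'   `data` list-column holds one stream tibble per channel.
#' @examples
#' s <- generate_session(subject_profile("s1", 1.3, 2.4),
#'                       config = session_config(), seed = 1,
#'                       schedule = generate_schedule(1, n_commands = 2))
#' s$channels
#' @export
generate_session <- function(profile, trial_id = 1,
                             config = session_config(), seed = 1,
                             schedule = NULL) {
  if (is.null(schedule)) schedule <- generate_schedule(sub_seed(seed, 1))
  speed <- simulate_speed(schedule, profile, fs = config$fs_speed,
                          seed = sub_seed(seed, 2),
                          noise_sd = config$speed_noise_sd)
  layout <- session_channels(config)
  fp <- synthesize_force_plates(speed, profile, seed = sub_seed(seed, 3),
                                config = config)
  data <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    spec <- layout[i, ]
    data[[i]] <- switch(
      spec$modality,
      semg = synthesize_semg(speed, spec, profile,
                             seed = sub_seed(seed, 10 + i), config = config),
      accel = synthesize_accelerometer(speed, spec, profile,
                                       seed = sub_seed(seed, 10 + i),
                                       config = config),
      force_plate = tibble::tibble(
        time_s = fp$time_s,
        value = if (spec$side == "left") fp$left_n else fp$right_n
      ),
      speed = speed
    )
  }
  layout$data <- data
  structure(
    list(
      subject_id = profile$subject_id,
      trial_id = as.integer(trial_id),
      profile = profile,
      schedule = schedule,
      config = config,
      seed = as.integer(seed),
      duration_s = schedule_duration(schedule),
      channels = layout
    ),
    class = "gait_session"
  )
}

#' Extract one channel's stream from a session
#'
#' @param session A `gait_session`.
#' @param channel_id Channel identifier (see [session_channels()]).
#' @return The channel's stream tibble.
#' @export
session_channel_data <- function(session, channel_id) {
  i <- match(channel_id, session$channels$channel_id)
  if (is.na(i)) abort(paste0("session has no channel `", channel_id, "`"))
  session$channels$data[[i]]
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf("<gait_session> subject %s, trial %d: %g s, %d channels, seed %d\n",
              x$subject_id, x$trial_id, x$duration_s, nrow(x$channels), x$seed))
  cat("  schedule:", paste(as.character(x$schedule$activity), collapse = " > "),
      "\n")
  invisible(x)
}

#' Generate a full synthetic study
#'
#' Default conditions: five subjects (the [default_profiles()] threshold
#' sets), six 150 s trials each, with command orders switched between trials
#' so every activity-to-activity transition occurs across a subject's trials.
#'
#' @param profiles List of [subject_profile()]s.
#' @param n_trials Trials per subject.
#' @param config A [session_config()].
#' @param seed Integer study seed; all sessions derive their seeds from it.
#' @return A `gait_study`: list of `gait_session` objects.
#' @export
generate_study <- function(profiles = default_profiles(), n_trials = 6,
                           config = session_config(), seed = 1) {
  sessions <- list()
  for (si in seq_along(profiles)) {
    schedules <- generate_schedules(n_trials, seed = sub_seed(seed, 1000 + si))
    for (tr in seq_len(n_trials)) {
      sessions[[length(sessions) + 1L]] <- generate_session(
        profiles[[si]], trial_id = tr, config = config,
        seed = sub_seed(seed, si * 100 + tr), schedule = schedules[[tr]]
      )
    }
  }
  structure(sessions, class = "gait_study")
}

#' Simulate a study and return its pooled feature matrix
#'
#' Equivalent to `study_features(generate_study(...))` but streams one
#' session at a time (generate, extract, discard), so full-length studies do
#' not hold thirty sessions of raw multi-rate signals in memory at once.
#'
#' @inheritParams generate_study
#' @param spec Feature spec passed to [extract_features()].
#' @param include_references Passed to [extract_features()].
#' @return Pooled feature matrix tibble.
#' @export
simulate_study_features <- function(profiles = default_profiles(), n_trials = 6,
                                    config = session_config(), seed = 1,
                                    spec = NULL, include_references = TRUE) {
  out <- list()
  for (si in seq_along(profiles)) {
    schedules <- generate_schedules(n_trials, seed = sub_seed(seed, 1000 + si))
    for (tr in seq_len(n_trials)) {
      s <- generate_session(profiles[[si]], trial_id = tr, config = config,
                            seed = sub_seed(seed, si * 100 + tr),
                            schedule = schedules[[tr]])
      out[[length(out) + 1L]] <- extract_features(
        s, spec = spec, include_references = include_references
      )
    }
  }
  dplyr::bind_rows(out)
}

#' @export
print.gait_study <- function(x, ...) {
  subj <- unique(vapply(x, function(s) s$subject_id, character(1)))
  cat(sprintf("<gait_study> %d sessions (%d subjects)\n", length(x), length(subj)))
  invisible(x)
}
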