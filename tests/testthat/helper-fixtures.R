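# Shared fixture builders. Everything is generated in code; short schedules
# keep the unit tests fast while the acceptance suite runs full-length trials.

tiny_profile <- function(id = "s1") subject_profile(id, walk_upper = 1.3, run_upper = 2.4)

fixed_schedule <- function(activities, duration_per = 5) {
  tibble::tibble(
    activity = factor(activities, levels = activity_levels()),
    start_s = (seq_along(activities) - 1) * duration_per,
    duration_s = duration_per
  )
}

# A short but complete session covering all four activities.
tiny_session <- function(seed = 1, config = session_config(), duration_per = 5,
                         profile = tiny_profile()) {
  generate_session(
    profile, trial_id = 1, config = config, seed = seed,
    schedule = fixed_schedule(c("stand", "walk", "run", "sprint"), duration_per)
  )
}

# Synthetic feature matrix with well-separated class blobs in `p` feature
# dimensions, organised as `n_trials` pseudo-trials; used for classifier
# contract tests without running the signal generator.
blob_features <- function(n_trials = 3, per_class = 25, p = 3, sep = 6,
                          seed = 1, classes = activity_levels(),
                          subject = "s1") {
  set.seed(seed)
  # deterministic, evenly spread class centers on a circle in the first two
  # feature dimensions
  ang <- 2 * pi * (seq_along(classes) - 1) / length(classes)
  centers <- cbind(cos(ang), sin(ang), matrix(0, length(classes), max(0, p - 2)))
  centers <- centers[, seq_len(p), drop = FALSE] * sep
  rows <- list()
  for (tr in seq_len(n_trials)) {
    for (ci in seq_along(classes)) {
      x <- matrix(rnorm(per_class * p), ncol = p) + rep(centers[ci, ], each = per_class)
      df <- tibble::as_tibble(as.data.frame(x))
      names(df) <- paste0("f", seq_len(p))
      df <- dplyr::mutate(
        df,
        subject_id = subject, trial_id = tr,
        window_start_s = seq_len(per_class) * 0.2,
        label = factor(classes[ci], levels = activity_levels()),
        .before = 1
      )
      rows[[length(rows) + 1L]] <- df
    }
  }
  dplyr::bind_rows(rows)
}
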