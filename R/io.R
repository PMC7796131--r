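## On-disk session dialect (version 1): one directory per trial holding a
## YAML `manifest.yaml` (subject profile, schedule, channel specs, config,
## seed) plus one tab-delimited file per channel (`time_s` and either
## `value` or `x`,`y`,`z`, or `speed_mps` for the belt-speed log).

SESSION_DIALECT_VERSION <- 1L

#' Write a session to a directory
#'
#' @param session A `gait_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    dialect_version = SESSION_DIALECT_VERSION,
    subject_id = session$subject_id,
    trial_id = session$trial_id,
    seed = session$seed,
    duration_s = session$duration_s,
    profile = unclass(session$profile),
    config = unclass(session$config),
    schedule = lapply(seq_len(nrow(session$schedule)), function(i) {
      list(activity = as.character(session$schedule$activity[i]),
           start_s = session$schedule$start_s[i],
           duration_s = session$schedule$duration_s[i])
    }),
    channels = lapply(seq_len(nrow(session$channels)), function(i) {
      ch <- session$channels[i, ]
      list(channel_id = ch$channel_id, modality = ch$modality,
           muscle = ch$muscle, segment = ch$segment, side = ch$side,
           sampling_rate = ch$sampling_rate)
    })
  )
  manifest$profile$preferred_speeds <- as.list(session$profile$preferred_speeds)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  for (i in seq_len(nrow(session$channels))) {
    readr::write_tsv(
      session$channels$data[[i]],
      file.path(dir, paste0(session$channels$channel_id[i], ".tsv")),
      progress = FALSE
    )
  }
  invisible(dir)
}

#' Read a session from a directory written by [write_session()]
#'
#' @param dir Session directory.
#' @return A `gait_session`.
#' @export
read_session <- function(dir) {
  mf <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  if (!identical(as.integer(mf$dialect_version), SESSION_DIALECT_VERSION)) {
    abort("unsupported session dialect version")
  }
  prof <- subject_profile(
    mf$profile$subject_id, mf$profile$walk_upper, mf$profile$run_upper,
    preferred_speeds = unlist(mf$profile$preferred_speeds),
    response_lag = mf$profile$response_lag,
    stride_frequency_base = mf$profile$stride_frequency_base
  )
  cfg <- do.call(session_config, mf$config[setdiff(names(mf$config), character(0))])
  schedule <- dplyr::bind_rows(lapply(mf$schedule, tibble::as_tibble))
  schedule$activity <- as_activity(schedule$activity)
  channels <- dplyr::bind_rows(lapply(mf$channels, tibble::as_tibble))
  channels$data <- lapply(channels$channel_id, function(id) {
    readr::read_tsv(file.path(dir, paste0(id, ".tsv")),
                    show_col_types = FALSE, progress = FALSE)
  })
  structure(
    list(subject_id = mf$subject_id, trial_id = as.integer(mf$trial_id),
         profile = prof, schedule = schedule, config = cfg,
         seed = as.integer(mf$seed), duration_s = mf$duration_s,
         channels = channels),
    class = "gait_session"
  )
}

#' Write / read a feature matrix as a delimited table
#'
#' @param fm Feature matrix tibble.
#' @param path File path (tab-separated).
#' @return `path` / the feature matrix.
#' @export
write_features <- function(fm, path) {
  out <- fm
  out$label <- as.character(out$label)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  fm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("label" %in% names(fm)) fm$label <- as_activity(fm$label)
  fm
}
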