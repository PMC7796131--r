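#' Create a subject profile
#'
#' A subject profile holds the per-subject speed thresholds that separate
#' walking, running and sprinting on a self-paced treadmill, the subject's
#' preferred (steady-state) speed for each commanded activity, and simple
#' gait parameters used by the signal generator. Thresholds follow the
#' half-open interval convention: walk is `(0, walk_upper]`, run is
#' `(walk_upper, run_upper]`, sprint is anything above `run_upper`.
#'
#' @param subject_id Label for the subject.
#' @param walk_upper Upper walking speed threshold in m/s (inclusive).
#' @param run_upper Upper running speed threshold in m/s (inclusive);
#'   speeds above it are sprinting.
#' @param preferred_speeds Optional named numeric vector with entries
#'   `stand`, `walk`, `run`, `sprint` giving mean self-paced speeds (m/s).
#'   Defaults place walking and running at their band midpoints and
#'   sprinting at `1.15 * run_upper` (the sprint band has no upper edge).
#' @param response_lag First-order time constant (seconds) with which the
#'   subject's speed follows a new command.
#' @param stride_frequency_base Stride frequency intercept in Hz; the
#'   generator adds a speed-proportional term on top.
#' @return An object of class `subject_profile`.
#' @examples
#' subject_profile("s1", walk_upper = 1.3, run_upper = 2.4)
#' @export
subject_profile <- function(subject_id, walk_upper, run_upper,
                            preferred_speeds = NULL,
                            response_lag = 1.5,
                            stride_frequency_base = 0.85) {
  stopifnot_scalar_number(walk_upper, "walk_upper")
  stopifnot_scalar_number(run_upper, "run_upper")
  if (!(0 < walk_upper && walk_upper < run_upper)) {
    abort("need 0 < walk_upper < run_upper")
  }
  if (response_lag <= 0) abort("`response_lag` must be positive")
  if (is.null(preferred_speeds)) {
    preferred_speeds <- c(
      stand  = 0,
      walk   = walk_upper / 2,
      run    = (walk_upper + run_upper) / 2,
      sprint = 1.15 * run_upper
    )
  }
  need <- activity_levels()
  if (!all(need %in% names(preferred_speeds))) {
    abort("`preferred_speeds` must name stand, walk, run and sprint")
  }
  ps <- preferred_speeds[need]
  ok <- ps[["stand"]] == 0 &&
    ps[["walk"]] > 0 && ps[["walk"]] <= walk_upper &&
    ps[["run"]] > walk_upper && ps[["run"]] <= run_upper &&
    ps[["sprint"]] > run_upper
  if (!ok) abort("preferred speeds must lie inside their activity bands")
  structure(
    list(
      subject_id = as.character(subject_id),
      walk_upper = walk_upper,
      run_upper = run_upper,
      preferred_speeds = ps,
      response_lag = response_lag,
      stride_frequency_base = stride_frequency_base
    ),
    class = "subject_profile"
  )
}

#' Default study subject profiles
#'
#' Five profiles whose walk/run speed thresholds reproduce the per-subject
#' labelling bands of the study design this package emulates (e.g. subject 2:
#' walk `(0, 1.6]`, run `(1.6, 3.3]` m/s). Preferred speeds sit at the band
#' midpoints.
#'
#' @return A named list of [subject_profile()] objects.
#' @export
default_profiles <- function() {
  thr <- list(
    subject1 = c(1.3, 2.4),
    subject2 = c(1.6, 3.3),
    subject3 = c(1.6, 2.8),
    subject4 = c(1.4, 2.5),
    subject5 = c(1.2, 2.7)
  )
  lapply(
    stats::setNames(names(thr), names(thr)),
    function(id) subject_profile(id, thr[[id]][1], thr[[id]][2])
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat("<subject_profile> ", x$subject_id, "\n", sep = "")
  cat(sprintf("  walk (0, %.2f], run (%.2f, %.2f], sprint (%.2f, Inf) m/s\n",
              x$walk_upper, x$walk_upper, x$run_upper, x$run_upper))
  cat(sprintf("  preferred: stand %.2f, walk %.2f, run %.2f, sprint %.2f m/s\n",
              x$preferred_speeds[["stand"]], x$preferred_speeds[["walk"]],
              x$preferred_speeds[["run"]], x$preferred_speeds[["sprint"]]))
  cat(sprintf("  response lag %.2f s, stride base %.2f Hz\n",
              x$response_lag, x$stride_frequency_base))
  invisible(x)
}
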