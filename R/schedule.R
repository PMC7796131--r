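#' Generate a command schedule for one trial
#'
#' Commands are drawn from stand/walk/run/sprint. The first four commands are
#' a seeded permutation of all four activities (so any schedule of at least
#' four commands contains every activity); subsequent commands follow a
#' least-used-transition greedy walk with seeded tie-breaking, which spreads
#' activity-to-activity transitions roughly evenly. Blocks are contiguous and
#' non-overlapping.
#'
#' @param seed Integer seed controlling the command order.
#' @param n_commands Number of commands (default 15).
#' @param duration_per Duration of each command block in seconds (default 10,
#'   giving the default 150 s trial).
#' @return A tibble with columns `activity` (factor), `start_s`, `duration_s`.
#' @examples
#' generate_schedule(seed = 1)
#' @export
generate_schedule <- function(seed = 1, n_commands = 15, duration_per = 10) {
  sch <- generate_schedules(n_trials = 1L, seed = seed,
                            n_commands = n_commands,
                            duration_per = duration_per)
  sch[[1L]]
}

#' Generate command schedules for a set of trials
#'
#' Like [generate_schedule()], but a single transition-usage ledger is shared
#' across all trials: the greedy walk always extends the least-used transition
#' out of the current activity, so across a default six-trial set every
#' ordered activity pair (including repeats) occurs at least once.
#'
#' @inheritParams generate_schedule
#' @param n_trials Number of trial schedules to generate.
#' @return A list of schedule tibbles, one per trial.
#' @export
generate_schedules <- function(n_trials = 6, seed = 1, n_commands = 15,
                               duration_per = 10) {
  if (n_trials < 1) abort("`n_trials` must be at least 1")
  if (n_commands < 1) abort("`n_commands` must be at least 1")
  stopifnot_scalar_number(duration_per, "duration_per")
  if (duration_per <= 0) abort("`duration_per` must be positive")

  acts <- activity_levels()
  counts <- matrix(0L, 4L, 4L, dimnames = list(acts, acts))
  out <- vector("list", n_trials)
  set.seed(as.integer(seed %% 2147483647))
  for (tr in seq_len(n_trials)) {
    head_n <- min(4L, n_commands)
    cmds <- sample(acts)[seq_len(head_n)]
    for (i in seq_len(head_n - 1L)) {
      counts[cmds[i], cmds[i + 1L]] <- counts[cmds[i], cmds[i + 1L]] + 1L
    }
    while (length(cmds) < n_commands) {
      prev <- cmds[length(cmds)]
      opts <- acts[counts[prev, ] == min(counts[prev, ])]
      nxt <- if (length(opts) == 1L) opts else sample(opts, 1L)
      counts[prev, nxt] <- counts[prev, nxt] + 1L
      cmds <- c(cmds, nxt)
    }
    out[[tr]] <- tibble::tibble(
      activity = as_activity(cmds),
      start_s = (seq_along(cmds) - 1) * duration_per,
      duration_s = duration_per
    )
  }
  out
}

#' Total duration of a schedule in seconds
#' @param schedule A schedule tibble from [generate_schedule()].
#' @return Scalar duration in seconds.
#' @export
schedule_duration <- function(schedule) {
  max(schedule$start_s + schedule$duration_s)
}

## Activity commanded at each time point (vectorised step lookup).
schedule_activity_at <- function(schedule, times) {
  idx <- findInterval(times, schedule$start_s)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(schedule)] <- nrow(schedule)
  schedule$activity[idx]
}
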