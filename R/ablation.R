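#' The eight canonical sensor-ablation cases
#'
#' Case 1 all sensors; Case 2 upper-leg units; Case 3 lower-leg units;
#' Cases 4 and 5 add the force plates to the upper- and lower-leg sets;
#' Case 6 the gastrocnemius units only; Case 7 one accelerometer per leg
#' segment (vastus medialis and tibialis anterior sites, both legs, 4 units,
#' accelerometer features only); Case 8 one accelerometer per shank (2
#' units). Units in Cases 1–6 contribute all their feature families (the
#' wearables combine an sEMG and an accelerometer); Cases 7–8 contribute ACC
#' features only.
#'
#' @return Tibble with `case_id`, `label`, list-column `muscles`, `families`
#'   (feature families contributed by each unit), and `force_plates` flag.
#' @export
sensor_cases <- function() {
  all_m <- c("gastrocnemius", "tibialis_anterior", "hamstring", "vastus_medialis")
  upper <- c("hamstring", "vastus_medialis")
  lower <- c("gastrocnemius", "tibialis_anterior")
  full_fam <- c("ACC", "MF", "H1", "H2", "H3")
  tibble::tibble(
    case_id = 1:8,
    label = c("all sensors", "upper leg", "lower leg",
              "upper leg + force plates", "lower leg + force plates",
              "gastrocnemius", "one accelerometer per segment",
              "one accelerometer per shank"),
    muscles = list(all_m, upper, lower, upper, lower, "gastrocnemius",
                   c("vastus_medialis", "tibialis_anterior"),
                   "tibialis_anterior"),
    families = c(rep(list(full_fam), 6), list("ACC"), list("ACC")),
    force_plates = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}

#' Feature specification for an ablation case
#'
#' Restricts the canonical feature spec to the channels and feature families
#' the case retains. Feature counts follow the conservation rule
#' `5 x (sEMG channels) + 1 x (accelerometer channels) + 2 x (force plates)`:
#' 44 for Case 1, 20 for Case 3, 2 for Case 8.
#'
#' @param case One row of [sensor_cases()] (or a tibble shaped like it).
#' @param channels Channel layout (default [session_channels()]).
#' @return Feature spec tibble (subset of [canonical_feature_spec()], order
#'   preserved).
#' @export
case_feature_spec <- function(case, channels = session_channels()) {
  if (nrow(case) != 1L) abort("`case` must be a single case row")
  spec <- canonical_feature_spec(channels)
  muscles <- case$muscles[[1]]
  fams <- case$families[[1]]
  ch <- channels
  keep_units <- ch$channel_id[ch$muscle %in% muscles]
  keep <- (spec$channel_id %in% keep_units & spec$family %in% fams) |
    (case$force_plates & spec$family %in% c("FPM", "FPSD"))
  spec[keep, ]
}

#' Cohen's d standardized mean difference
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with the pooled SD
#' `sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#' A zero pooled SD yields `NA` with a warning.
#'
#' @param a,b Numeric vectors (each at least 2 values).
#' @return Scalar effect size.
#' @examples
#' cohens_d(c(2, 4), c(1, 3))
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) abort("each group needs at least 2 values")
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) {
    warning("zero pooled SD: effect size undefined", call. = FALSE)
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sp
}

#' Conventional effect-size label for Cohen's d
#'
#' `|d| < 0.2` negligible, `< 0.5` small, `< 0.8` medium, otherwise large
#' (boundary values take the label of the threshold they reach).
#'
#' @param d Numeric vector of effect sizes.
#' @return Character vector of labels (`NA` in, `NA` out).
#' @export
effect_size_label <- function(d) {
  a <- abs(d)
  out <- ifelse(a < 0.2, "negligible",
         ifelse(a < 0.5, "small",
         ifelse(a < 0.8, "medium", "large")))
  out[is.na(d)] <- NA_character_
  out
}

#' Run the sensor-ablation analysis
#'
#' For each case, restricts the pooled feature matrix to the case's feature
#' columns and runs the full leave-one-trial-out pipeline (normalize, PCA,
#' Gaussian SVM). Per-case subject-by-fold accuracies are compared pairwise
#' with Cohen's d, for both raw and run/sprint-merged accuracy.
#'
#' @param fm Pooled full-sensor feature matrix from [study_features()].
#' @param cases Case table (default all eight canonical cases); pass a
#'   subset of [sensor_cases()] rows to restrict.
#' @param channels Channel layout used to build case feature specs.
#' @param k_components,cost,gamma,seed Passed to [cross_validate()].
#' @return A `gait_ablation`: list with per-case `cv` results, the pooled
#'   `accuracy` fold tibble, and an `effects` tibble of pairwise Cohen's d
#'   (`d_raw`, `d_merged`) with effect-size labels for the merged regime.
#' @export
run_ablation <- function(fm, cases = sensor_cases(),
                         channels = session_channels(),
                         k_components = 3, cost = 1, gamma = NULL, seed = 1) {
  meta <- intersect(META_COLS, names(fm))
  cvs <- vector("list", nrow(cases))
  acc <- list()
  for (i in seq_len(nrow(cases))) {
    case <- cases[i, ]
    spec <- case_feature_spec(case, channels)
    missing_f <- setdiff(spec$feature_id, names(fm))
    if (length(missing_f) > 0) {
      abort(paste0("case ", case$case_id, ": feature matrix lacks ",
                   paste(missing_f, collapse = ", ")))
    }
    case_fm <- fm[c(meta, spec$feature_id)]
    cvs[[i]] <- cross_validate(case_fm, k_components = k_components,
                               cost = cost, gamma = gamma,
                               seed = sub_seed(seed, case$case_id))
    acc[[i]] <- dplyr::mutate(cvs[[i]]$folds, case_id = case$case_id,
                              case_label = case$label)
  }
  names(cvs) <- paste0("case", cases$case_id)
  acc <- dplyr::bind_rows(acc)

  if (nrow(cases) < 2L) {
    return(structure(
      list(cases = cases, cv = cvs, accuracy = acc,
           effects = tibble::tibble(
             case_a = integer(), case_b = integer(), comparison = character(),
             d_raw = double(), d_merged = double(), effect_size = character()
           )),
      class = "gait_ablation"
    ))
  }
  pairs <- utils::combn(seq_len(nrow(cases)), 2L)
  eff <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    ai <- acc[acc$case_id == cases$case_id[i], ]
    aj <- acc[acc$case_id == cases$case_id[j], ]
    d_raw <- cohens_d(ai$accuracy, aj$accuracy)
    d_merged <- cohens_d(ai$accuracy_merged, aj$accuracy_merged)
    tibble::tibble(
      case_a = cases$case_id[i], case_b = cases$case_id[j],
      comparison = paste0("Case ", cases$case_id[i], " vs. Case ",
                          cases$case_id[j]),
      d_raw = d_raw, d_merged = d_merged,
      effect_size = effect_size_label(d_merged)
    )
  })
  structure(
    list(cases = cases, cv = cvs, accuracy = acc,
         effects = dplyr::bind_rows(eff)),
    class = "gait_ablation"
  )
}

#' @export
print.gait_ablation <- function(x, ...) {
  cat(sprintf("<gait_ablation> %d cases, %d folds each\n",
              nrow(x$cases), nrow(x$accuracy) / nrow(x$cases)))
  med <- dplyr::summarise(
    dplyr::group_by(x$accuracy, .data$case_id, .data$case_label),
    median_merged = median(.data$accuracy_merged), .groups = "drop"
  )
  for (i in seq_len(nrow(med))) {
    cat(sprintf("  case %d (%s): median merged accuracy %.1f%%\n",
                med$case_id[i], med$case_label[i], 100 * med$median_merged[i]))
  }
  invisible(x)
}
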