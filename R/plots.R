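## ggplot2 displays for the main result types.

#' Plot a session's speed trace with its activity labels
#'
#' @param object A `gait_session`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gait_session
#' @export
autoplot.gait_session <- function(object, ...) {
  sp <- session_channel_data(object, "treadmill_speed")
  lab <- session_labels(object)
  df <- dplyr::mutate(sp, label = lab$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$speed_mps)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 0.3) +
    ggplot2::labs(
      x = "time (s)", y = "belt speed (m/s)", colour = "activity",
      title = sprintf("subject %s, trial %d", object$subject_id, object$trial_id)
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a median component-angle matrix
#'
#' @param object An `angle_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot angle_matrix
#' @export
autoplot.angle_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$component_b),
                                   y = factor(.data$component_a),
                                   fill = .data$angle_deg)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f°", .data$angle_deg)), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 90), name = "angle (°)") +
    ggplot2::labs(x = "component (other trial)", y = "component",
                  title = "median angles between principal components") +
    ggplot2::theme_minimal()
}

#' Box plot of per-fold cross-validation accuracies
#'
#' @param object A `gait_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gait_cv
#' @export
autoplot.gait_cv <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds,
                            c("accuracy", "accuracy_merged"),
                            names_to = "regime", values_to = "accuracy")
  df$regime <- ifelse(df$regime == "accuracy", "raw", "run/sprint merged")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$regime, y = .data$accuracy)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "fold accuracy",
                  title = "leave-one-trial-out accuracy") +
    ggplot2::theme_minimal()
}

#' Box plot of per-case ablation accuracies
#'
#' @param object A `gait_ablation`.
#' @param merged Plot run/sprint-merged accuracies (default) or raw.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gait_ablation
#' @export
autoplot.gait_ablation <- function(object, merged = TRUE, ...) {
  df <- object$accuracy
  df$acc <- if (merged) df$accuracy_merged else df$accuracy
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$case_id), y = .data$acc)) +
    ggplot2::geom_boxplot() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(
      x = "ablation case", y = "fold accuracy",
      title = sprintf("classification accuracy per sensor case (%s)",
                      if (merged) "run/sprint confusion allowed" else "raw")
    ) +
    ggplot2::theme_minimal()
}
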