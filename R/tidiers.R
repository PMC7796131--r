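## broom-style tidiers for the package's result objects.

#' Tidy a fitted PCA
#'
#' @param x A `gait_pca`.
#' @param matrix `"loadings"` (long feature x component table) or
#'   `"explained"` (per-component variance fractions).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gait_pca
#' @export
tidy.gait_pca <- function(x, matrix = c("loadings", "explained"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "explained") {
    return(tibble::tibble(
      component = seq_along(x$explained),
      explained_variance = x$explained,
      cumulative = cumsum(x$explained)
    ))
  }
  w <- x$loadings
  tibble::tibble(
    feature = rep(rownames(w), times = ncol(w)),
    component = rep(seq_len(ncol(w)), each = nrow(w)),
    loading = as.vector(w)
  )
}

#' @method glance gait_pca
#' @export
glance.gait_pca <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_ids),
    n_components = ncol(x$loadings),
    explained_pc1_3 = sum(x$explained[seq_len(min(3, length(x$explained)))])
  )
}

#' Tidy an angle matrix into long form
#'
#' @param x An `angle_matrix`.
#' @param ... Unused.
#' @return Tibble with `component_a`, `component_b`, `angle_deg`, `like`.
#' @method tidy angle_matrix
#' @export
tidy.angle_matrix <- function(x, ...) {
  k <- nrow(x)
  tibble::tibble(
    component_a = rep(seq_len(k), times = k),
    component_b = rep(seq_len(k), each = k),
    angle_deg = as.vector(unclass(x)),
    like = rep(seq_len(k), times = k) == rep(seq_len(k), each = k)
  )
}

#' @method glance pc_correlations
#' @export
glance.pc_correlations <- function(x, ...) {
  tibble::tibble(
    component = attr(x, "component"),
    reference = attr(x, "reference"),
    median_rho = median(x$rho),
    iqr_rho = stats::IQR(x$rho),
    n_trials = nrow(x)
  )
}

#' Tidy a cross-validation result (per-fold accuracies)
#'
#' @param x A `gait_cv`.
#' @param ... Unused.
#' @return The folds tibble.
#' @method tidy gait_cv
#' @export
tidy.gait_cv <- function(x, ...) x$folds

#' @method glance gait_cv
#' @export
glance.gait_cv <- function(x, ...) {
  tibble::tibble(
    n_folds = nrow(x$folds),
    median_accuracy = x$summary$raw[["median"]],
    mad_accuracy = x$summary$raw[["mad"]],
    median_accuracy_merged = x$summary$merged[["median"]],
    mad_accuracy_merged = x$summary$merged[["mad"]]
  )
}

#' Tidy an ablation result (per-case, per-fold accuracies)
#'
#' @param x A `gait_ablation`.
#' @param ... Unused.
#' @return The pooled accuracy tibble.
#' @method tidy gait_ablation
#' @export
tidy.gait_ablation <- function(x, ...) x$accuracy

#' @method glance gait_ablation
#' @export
glance.gait_ablation <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$accuracy, .data$case_id, .data$case_label),
    median_accuracy = median(.data$accuracy),
    median_accuracy_merged = median(.data$accuracy_merged),
    mad_accuracy_merged = median(abs(.data$accuracy_merged -
                                       median(.data$accuracy_merged))),
    .groups = "drop"
  )
}
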