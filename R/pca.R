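#' Fit principal component analysis on a normalized feature matrix
#'
#' Components are ordered by decreasing explained variance, with a
#' deterministic sign convention: each loading column's largest-magnitude
#' entry is made positive (a principal axis is direction-ambiguous, so the
#' convention fixes a representative without changing the subspace).
#'
#' @param fm Feature matrix tibble (typically after [apply_normalizer()]) or
#'   a plain numeric matrix.
#' @return A `gait_pca`: list with `loadings` (features x components,
#'   orthonormal columns), `scores` (windows x components), `center`
#'   (training means), `explained` (variance fractions) and `feature_ids`.
#' @export
fit_pca <- function(fm) {
  m <- if (is.matrix(fm)) fm else as.matrix(fm[feature_cols(fm)])
  if (is.null(colnames(m))) colnames(m) <- paste0("f", seq_len(ncol(m)))
  if (nrow(m) < 2L) abort("need at least 2 rows to fit a PCA")
  p <- prcomp(m, center = TRUE, scale. = FALSE)
  w <- p$rotation
  sc <- p$x
  for (j in seq_len(ncol(w))) {
    if (w[which.max(abs(w[, j])), j] < 0) {
      w[, j] <- -w[, j]
      sc[, j] <- -sc[, j]
    }
  }
  ev <- p$sdev^2
  structure(
    list(
      loadings = w,
      scores = sc,
      center = p$center,
      explained = ev / sum(ev),
      feature_ids = colnames(m)
    ),
    class = "gait_pca"
  )
}

#' @export
print.gait_pca <- function(x, ...) {
  cat(sprintf("<gait_pca> %d features, %d components; PC1-3 explain %.1f%%\n",
              length(x$feature_ids), ncol(x$loadings),
              100 * sum(x$explained[seq_len(min(3, length(x$explained)))]))
  )
  invisible(x)
}

#' Project new data into a fitted PCA space
#'
#' Test data are centered with the model's training means and projected onto
#' the training loadings; no new PCA is fit on the test data.
#'
#' @param object A `gait_pca`.
#' @param newdata Feature matrix tibble or numeric matrix with the model's
#'   feature columns.
#' @param ... Unused.
#' @return Score matrix (rows x components).
#' @export
predict.gait_pca <- function(object, newdata, ...) {
  m <- if (is.matrix(newdata)) newdata else as.matrix(newdata[feature_cols(newdata)])
  if (!identical(colnames(m), object$feature_ids)) {
    if (!setequal(colnames(m), object$feature_ids)) {
      abort("feature columns do not match the PCA model")
    }
    m <- m[, object$feature_ids, drop = FALSE]
  }
  sweep(m, 2L, object$center) %*% object$loadings
}

#' @rdname predict.gait_pca
#' @param model A `gait_pca`.
#' @param fm Feature matrix to project.
#' @export
pca_transform <- function(model, fm) predict(model, fm)

#' Angle between two principal-component loading vectors
#'
#' `acos` of the clamped dot product of the unit-normalized vectors, in
#' degrees within `[0, 180]`.
#'
#' @param w_a,w_b Loading vectors of equal dimension.
#' @return Angle in degrees.
#' @examples
#' component_angle(c(1, 0), c(1, 1) / sqrt(2))
#' @export
component_angle <- function(w_a, w_b) {
  if (length(w_a) != length(w_b)) abort("loading vectors differ in dimension")
  d <- sum(w_a * w_b) / (sqrt(sum(w_a^2)) * sqrt(sum(w_b^2)))
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}

#' Fold an angle to account for principal-axis sign ambiguity
#'
#' A principal axis represents variance in both directions, so for
#' like-component comparisons (PC i vs PC i from another trial) angles above
#' 90 degrees are replaced by their supplement. Non-like comparisons are
#' reported unfolded.
#'
#' @param theta Angle in degrees, within `[0, 180]`.
#' @param like_components Fold only when comparing same-index components.
#' @return Angle in degrees.
#' @export
fold_angle <- function(theta, like_components = TRUE) {
  if (any(theta < 0 | theta > 180)) abort("`theta` must lie in [0, 180] degrees")
  if (like_components) ifelse(theta > 90, 180 - theta, theta) else theta
}

#' Median component-angle matrix across trial/subject pairs
#'
#' For every unordered pair of PCA models and every component pair
#' `(i, j) <= k`, computes the angle between loading vectors (folded to
#' `[0, 90]` degrees when `i == j`), then reports the median over all model
#' pairs. Small diagonal entries relative to near-orthogonal off-diagonals
#' indicate that like-components span similar directions across trials.
#'
#' @param models List of `gait_pca` models sharing one feature space (at
#'   least two).
#' @param k Number of leading components to compare (default 3).
#' @return A k x k matrix of class `angle_matrix` (degrees) with an
#'   `n_pairs` attribute.
#' @export
angle_matrix <- function(models, k = 3) {
  if (length(models) < 2L) abort("need at least two PCA models")
  fids <- models[[1]]$feature_ids
  same <- vapply(models, function(m) identical(m$feature_ids, fids), logical(1))
  if (!all(same)) abort("all PCA models must share one feature space")
  k <- min(k, ncol(models[[1]]$loadings))
  pairs <- utils::combn(length(models), 2L)
  acc <- array(NA_real_, c(k, k, ncol(pairs)))
  for (p in seq_len(ncol(pairs))) {
    wa <- models[[pairs[1, p]]]$loadings
    wb <- models[[pairs[2, p]]]$loadings
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        th <- component_angle(wa[, i], wb[, j])
        acc[i, j, p] <- fold_angle(th, like_components = i == j)
      }
    }
  }
  out <- apply(acc, c(1, 2), median)
  dimnames(out) <- list(paste0("PC", seq_len(k)), paste0("PC", seq_len(k)))
  structure(out, class = c("angle_matrix", "matrix"), n_pairs = ncol(pairs))
}

#' Absolute correlation between component scores and a reference series
#'
#' The sign of a principal component is arbitrary, so the absolute value of
#' the (by default Pearson) correlation is reported.
#'
#' @param scores Numeric vector of per-window component scores.
#' @param reference Numeric vector of the per-window reference (e.g. mean
#'   treadmill speed, or left-minus-right mean plate force).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Absolute correlation in `[0, 1]`.
#' @export
pc_correlation <- function(scores, reference, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(scores) != length(reference)) abort("inputs differ in length")
  if (sd(scores) == 0 || sd(reference) == 0) {
    abort("correlation undefined for constant input")
  }
  abs(cor(scores, reference, method = method))
}

## Per-trial PCA models from a pooled feature matrix: each trial is z-scored
## on its own windows, then a PCA is fit per trial.
per_trial_models <- function(fm) {
  groups <- dplyr::group_split(dplyr::group_by(fm, .data$subject_id, .data$trial_id))
  lapply(groups, function(g) fit_pca(apply_normalizer(g, fit_normalizer(g))))
}

#' Study-wide median angle matrix
#'
#' Fits a per-trial PCA (per-trial z-scoring) for every session in the
#' pooled feature matrix and returns the median folded angle matrix over all
#' unordered trial/subject pairs.
#'
#' @param fm Pooled feature matrix from [study_features()].
#' @param k Components to compare.
#' @return An `angle_matrix`.
#' @export
study_angle_matrix <- function(fm, k = 3) {
  angle_matrix(per_trial_models(fm), k = k)
}

#' Per-trial correlations between a principal component and a reference
#'
#' For each trial: z-score the trial's windows, fit a PCA, and correlate the
#' chosen component's scores with the windowed reference series (mean
#' treadmill speed, or mean left-minus-right plate force). Absolute
#' correlations are returned; summarize with [glance()].
#'
#' @param fm Pooled feature matrix (with reference columns, see
#'   [extract_features()]).
#' @param component Component index (1 for the speed diagnostic, 2 for the
#'   force-difference diagnostic).
#' @param reference `"speed"` or `"force_diff"`.
#' @param method Correlation estimator.
#' @return Tibble of class `pc_correlations` with `subject_id`, `trial_id`,
#'   `rho`.
#' @export
study_pc_correlations <- function(fm, component = 1,
                                  reference = c("speed", "force_diff"),
                                  method = c("pearson", "spearman")) {
  reference <- match.arg(reference)
  method <- match.arg(method)
  ref_col <- if (reference == "speed") "speed_mean_mps" else "fp_diff_mean_n"
  if (!ref_col %in% names(fm)) {
    abort("feature matrix lacks the reference columns; extract with include_references = TRUE")
  }
  groups <- dplyr::group_split(dplyr::group_by(fm, .data$subject_id, .data$trial_id))
  rows <- lapply(groups, function(g) {
    model <- fit_pca(apply_normalizer(g, fit_normalizer(g)))
    tibble::tibble(
      subject_id = g$subject_id[1],
      trial_id = g$trial_id[1],
      rho = pc_correlation(model$scores[, component], g[[ref_col]],
                           method = method)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pc_correlations", class(out))
  attr(out, "component") <- component
  attr(out, "reference") <- reference
  out
}
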