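#' Merge running and sprinting into one label
#'
#' Running and sprinting differ mainly in speed rather than in gait
#' biomechanics, so accuracy is also reported with run/sprint confusion
#' allowed: both labels map to `run_sprint`; stand and walk are unchanged.
#'
#' @param labels Factor or character vector over [activity_levels()].
#' @return Factor over the merged three-level set.
#' @export
merge_run_sprint <- function(labels) {
  x <- as.character(labels)
  bad <- setdiff(unique(x), activity_levels())
  if (length(bad) > 0) {
    abort(paste0("unknown activity label(s): ", paste(bad, collapse = ", ")))
  }
  x[x %in% c("run", "sprint")] <- "run_sprint"
  factor(x, levels = activity_levels(merged = TRUE))
}

#' One-vs-rest sensitivity and specificity from a confusion matrix
#'
#' Sensitivity is TP / (TP + FN), specificity TN / (TN + FP), per class.
#' Empty denominators give `NA` (undefined), never zero.
#'
#' @param cm Square confusion matrix, rows = truth, columns = prediction.
#' @param class Optional single class name; by default all classes.
#' @return Tibble with `class`, `sensitivity`, `specificity`, `support`.
#' @export
sensitivity_specificity <- function(cm, class = NULL) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) abort("confusion matrix must be square")
  if (any(cm < 0)) abort("confusion matrix must be non-negative")
  classes <- rownames(cm)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(cm)))
  if (!is.null(class)) {
    if (!class %in% classes) abort("unknown class")
    keep <- class
  } else {
    keep <- classes
  }
  total <- sum(cm)
  rows <- lapply(keep, function(cl) {
    i <- match(cl, classes)
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    tibble::tibble(
      class = cl,
      sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
      specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
      support = tp + fn
    )
  })
  dplyr::bind_rows(rows)
}

#' Median and (unscaled) median absolute deviation
#'
#' @param x Numeric vector with at least one value.
#' @return Named vector `c(median, mad)` with
#'   `mad = median(|x - median(x)|)`, no consistency scaling.
#' @examples
#' median_mad(1:5)
#' @export
median_mad <- function(x) {
  if (length(x) == 0L) abort("need at least one value")
  m <- median(x)
  c(median = m, mad = median(abs(x - m)))
}

## Gaussian-kernel scale by the median pairwise distance heuristic on the
## training scores; subsampling (deterministic, evenly spaced) caps the cost.
rbf_gamma <- function(scores, max_rows = 500L) {
  n <- nrow(scores)
  if (n > max_rows) {
    scores <- scores[round(seq(1, n, length.out = max_rows)), , drop = FALSE]
  }
  sigma <- median(stats::dist(scores))
  if (sigma <= 0) sigma <- 1
  1 / (2 * sigma^2)
}

## Compact numeric fingerprint of a fitted SVM, to check that test-set
## corruption never touches the trained model.
svm_fingerprint <- function(fit) {
  round(sum(fit$coefs^2) + sum(fit$rho^2) + fit$tot.nSV, 9)
}

#' Leave-one-trial-out cross-validated Gaussian-SVM classification
#'
#' For each subject, whole trials are reserved one at a time for testing.
#' Per fold: a z-score normalizer and a PCA are fit on the training windows
#' only, the first `k_components` scores train a multiclass (one-vs-one)
#' Gaussian-kernel SVM, and the held-out trial is normalized and projected
#' with the training statistics before prediction. Accuracy is reported both
#' raw (four classes) and with run/sprint confusion allowed.
#'
#' @param fm Pooled feature matrix (one or more subjects, >= 2 trials each).
#' @param k_components Leading principal components kept (truncated to the
#'   number of features, so tiny sensor sets remain runnable).
#' @param cost SVM box constraint.
#' @param gamma Gaussian-kernel scale; default is the median pairwise
#'   distance heuristic per fold.
#' @param seed Integer seed (the fold pipeline is deterministic; the seed
#'   pins any libsvm-internal ordering).
#' @return A `gait_cv`: `folds` tibble (per subject x held-out trial:
#'   `accuracy`, `accuracy_merged`, `n_test`, `model_fingerprint`), pooled
#'   4x4 and merged 3x3 confusion matrices, per-class
#'   sensitivity/specificity, and median/MAD summaries.
#' @export
cross_validate <- function(fm, k_components = 3, cost = 1, gamma = NULL,
                           seed = 1) {
  cols <- feature_cols(fm)
  k <- min(k_components, length(cols))
  lv <- activity_levels()
  lvm <- activity_levels(merged = TRUE)
  conf <- matrix(0, 4, 4, dimnames = list(truth = lv, pred = lv))
  conf_m <- matrix(0, 3, 3, dimnames = list(truth = lvm, pred = lvm))
  folds <- list()
  set.seed(seed)
  for (subj in unique(fm$subject_id)) {
    sub_fm <- fm[fm$subject_id == subj, ]
    trials <- sort(unique(sub_fm$trial_id))
    if (length(trials) < 2L) abort("need at least 2 trials per subject")
    for (tr in trials) {
      train <- sub_fm[sub_fm$trial_id != tr, ]
      test <- sub_fm[sub_fm$trial_id == tr, ]
      train_lab <- factor(as.character(train$label), levels = lv)
      if (dplyr::n_distinct(train$label) < length(lv)) {
        warning(sprintf("subject %s fold %s: class missing from training; fold skipped",
                        subj, tr), call. = FALSE)
        next
      }
      norm <- fit_normalizer(train)
      pca <- fit_pca(apply_normalizer(train, norm))
      tr_scores <- pca$scores[, seq_len(k), drop = FALSE]
      g <- if (is.null(gamma)) rbf_gamma(tr_scores) else gamma
      fit <- e1071::svm(tr_scores, train_lab, kernel = "radial",
                        cost = cost, gamma = g, scale = FALSE)
      te_scores <- predict(pca, apply_normalizer(test, norm))[, seq_len(k), drop = FALSE]
      pred <- predict(fit, te_scores)
      truth <- factor(as.character(test$label), levels = lv)
      acc <- mean(pred == truth)
      pred_m <- merge_run_sprint(pred)
      truth_m <- merge_run_sprint(truth)
      acc_m <- mean(pred_m == truth_m)
      conf <- conf + table(truth, pred)
      conf_m <- conf_m + table(truth_m, pred_m)
      folds[[length(folds) + 1L]] <- tibble::tibble(
        subject_id = subj, trial_id = tr, n_test = nrow(test),
        accuracy = acc, accuracy_merged = acc_m,
        model_fingerprint = svm_fingerprint(fit)
      )
    }
  }
  folds <- dplyr::bind_rows(folds)
  structure(
    list(
      folds = folds,
      confusion = conf,
      confusion_merged = conf_m,
      class_stats = sensitivity_specificity(conf),
      class_stats_merged = sensitivity_specificity(conf_m),
      summary = list(
        raw = median_mad(folds$accuracy),
        merged = median_mad(folds$accuracy_merged)
      ),
      k_components = k
    ),
    class = "gait_cv"
  )
}

#' @export
print.gait_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<gait_cv> %d folds, %d components\n", nrow(x$folds), x$k_components))
  cat(sprintf("  raw accuracy:    median %.1f%% (MAD %.1f%%)\n",
              100 * s$raw[["median"]], 100 * s$raw[["mad"]]))
  cat(sprintf("  merged accuracy: median %.1f%% (MAD %.1f%%)\n",
              100 * s$merged[["median"]], 100 * s$merged[["mad"]]))
  invisible(x)
}
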