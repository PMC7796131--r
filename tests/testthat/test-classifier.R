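test_that("run/sprint merging forgives only run-sprint confusion", {
  expect_equal(as.character(merge_run_sprint(c("run", "sprint"))),
               c("run_sprint", "run_sprint"))
  truth <- merge_run_sprint("sprint")
  pred <- merge_run_sprint("run")
  expect_true(truth == pred)  # counted correct after merging
  expect_false(merge_run_sprint("walk") == merge_run_sprint("run"))
  expect_equal(as.character(merge_run_sprint(rep("stand", 3))), rep("stand", 3))
  expect_error(merge_run_sprint("jog"), "unknown")
})

test_that("sensitivity and specificity follow one-vs-rest counting", {
  perfect <- diag(c(5, 8, 3, 4))
  rownames(perfect) <- colnames(perfect) <- activity_levels()
  ss <- sensitivity_specificity(perfect)
  expect_true(all(ss$sensitivity == 1) && all(ss$specificity == 1))

  cm <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  one <- sensitivity_specificity(cm, class = "a")
  expect_equal(one$sensitivity, 0.8)
  expect_equal(one$specificity, 0.9)

  empty <- matrix(c(0, 0, 2, 3), 2, byrow = TRUE,
                  dimnames = list(c("a", "b"), c("a", "b")))
  expect_true(is.na(sensitivity_specificity(empty, "a")$sensitivity))
  expect_error(sensitivity_specificity(matrix(1, 2, 3)), "square")
})

test_that("sensitivity/specificity match direct counting on random labelings", {
  set.seed(6)
  lv <- activity_levels()
  for (i in 1:50) {
    truth <- factor(sample(lv, 60, replace = TRUE), levels = lv)
    pred <- factor(sample(lv, 60, replace = TRUE), levels = lv)
    cm <- table(truth, pred)
    cl <- sample(lv, 1)
    got <- sensitivity_specificity(cm, class = cl)
    want <- oracle_sens_spec(as.character(truth), as.character(pred), cl)
    expect_equal(got$sensitivity, unname(want["sensitivity"]))
    expect_equal(got$specificity, unname(want["specificity"]))
  }
})

test_that("median and MAD are unscaled", {
  expect_equal(median_mad(1:5), c(median = 3, mad = 1))
  expect_equal(median_mad(rep(7, 4)), c(median = 7, mad = 0))
  expect_equal(median_mad(2.5), c(median = 2.5, mad = 0))
  expect_error(median_mad(numeric(0)), "at least one")
})

test_that("well-separated classes are classified perfectly, trial by trial", {
  fm <- blob_features(n_trials = 3, per_class = 25, sep = 8, seed = 7)
  cv <- cross_validate(fm, seed = 1)
  expect_equal(nrow(cv$folds), 3)
  expect_true(all(cv$folds$accuracy == 1))
  expect_true(all(cv$folds$accuracy_merged >= cv$folds$accuracy))
  expect_equal(sum(cv$confusion), nrow(fm))
})

test_that("uninformative features land at chance level for four balanced classes", {
  accs <- vapply(1:20, function(seed) {
    fm <- blob_features(n_trials = 2, per_class = 40, sep = 0, seed = seed)
    mean(cross_validate(fm, seed = seed)$folds$accuracy)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.25), 0.05)
})

test_that("merged accuracy never falls below raw accuracy", {
  for (seed in 1:5) {
    fm <- blob_features(n_trials = 2, per_class = 20, sep = 1.5, seed = seed)
    cv <- cross_validate(fm, seed = seed)
    expect_true(all(cv$folds$accuracy_merged >= cv$folds$accuracy - 1e-12))
  }
})

test_that("test-trial contents never influence the trained fold model", {
  fm <- blob_features(n_trials = 3, per_class = 20, sep = 2, seed = 9)
  cv <- cross_validate(fm, seed = 1)

  # permute the rows of held-out trial 1: that fold is unchanged
  idx1 <- which(fm$trial_id == 1)
  set.seed(1)
  fm_perm <- fm
  fm_perm[idx1, ] <- fm_perm[sample(idx1), ]
  cv_perm <- cross_validate(fm_perm, seed = 1)
  f1 <- which(cv$folds$trial_id == 1)
  expect_equal(cv_perm$folds$accuracy[f1], cv$folds$accuracy[f1])
  expect_equal(cv_perm$folds$model_fingerprint[f1], cv$folds$model_fingerprint[f1])

  # corrupt the labels of held-out trial 1: its fold's model is unchanged,
  # its reported accuracy is not
  fm_bad <- fm
  fm_bad$label[idx1] <- factor(
    sample(activity_levels(), length(idx1), replace = TRUE),
    levels = activity_levels()
  )
  cv_bad <- cross_validate(fm_bad, seed = 1)
  f1 <- which(cv$folds$trial_id == 1)
  expect_equal(cv_bad$folds$model_fingerprint[f1], cv$folds$model_fingerprint[f1])
  expect_false(cv_bad$folds$accuracy[f1] == cv$folds$accuracy[f1])
})

test_that("a training fold missing a class is skipped with a warning", {
  fm <- blob_features(n_trials = 2, per_class = 10, seed = 10)
  fm <- fm[!(fm$trial_id == 2 & fm$label == "sprint"), ]
  # when trial 2 is held out, training (trial 1) has all classes; when trial 1
  # is held out, training lacks sprint -> that fold is skipped
  expect_warning(cv <- cross_validate(fm, seed = 1), "missing")
  expect_equal(nrow(cv$folds), 1)
  expect_equal(cv$folds$trial_id, 2)
})

test_that("specificity tends to exceed sensitivity under class imbalance", {
  diffs <- vapply(1:10, function(seed) {
    set.seed(seed)
    fm <- blob_features(n_trials = 2, per_class = 30, sep = 1.2, seed = seed)
    # imbalance: thin out sprint windows heavily (per trial, so every training
    # fold keeps all classes), as in fatigue-limited trials
    drop <- unlist(lapply(unique(fm$trial_id), function(tr) {
      rows <- which(fm$label == "sprint" & fm$trial_id == tr)
      rows[seq_len(floor(length(rows) * 0.8))]
    }))
    cv <- cross_validate(fm[-drop, ], seed = seed)
    st <- cv$class_stats
    mean(st$specificity, na.rm = TRUE) - mean(st$sensitivity, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("component truncation keeps tiny feature sets runnable", {
  fm <- blob_features(n_trials = 2, per_class = 15, p = 2, sep = 6, seed = 11)
  cv <- cross_validate(fm, k_components = 3, seed = 1)
  expect_equal(cv$k_components, 2)
  expect_true(all(cv$folds$accuracy == 1))
})
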