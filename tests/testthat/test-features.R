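test_that("sliding windows follow the step formula and drop trailing partials", {
  expect_equal(length(sliding_windows(150, 0.5, 0.30)), 748)
  expect_equal(sliding_windows(0.5), 0)
  expect_equal(length(sliding_windows(0.4)), 0)
  expect_equal(sliding_windows(1.0, 0.5, 0.30), c(0, 0.2, 0.4))
  expect_error(sliding_windows(10, 0.5, 0.5), "overlap")
  expect_error(sliding_windows(10, 0.5, 0.6), "overlap")
})

test_that("sliding windows agree with a brute-force enumeration oracle", {
  set.seed(1)
  for (i in 1:50) {
    w <- runif(1, 0.1, 2)
    ov <- runif(1, 0, w * 0.95)
    dur <- runif(1, 0, 30)
    got <- sliding_windows(dur, w, ov)
    expect_equal(got, oracle_windows(dur, w, w - ov), tolerance = 1e-9,
                 label = sprintf("case %d (T=%.3f w=%.3f ov=%.3f)", i, dur, w, ov))
  }
})

test_that("accelerometer window feature is the mean per-sample norm", {
  expect_equal(acc_feature(cbind(3, 4, 0)), 5)
  expect_equal(acc_feature(matrix(0, 10, 3)), 0)
  expect_equal(acc_feature(rbind(c(1, 0, 0), c(0, 2, 0))), 1.5)
  expect_error(acc_feature(matrix(0, 0, 3)), "empty")
})

test_that("force-plate window features are sample mean and SD", {
  expect_equal(fp_features(rep(700, 50)), c(mean = 700, sd = 0))
  expect_equal(fp_features(c(600, 800)),
               c(mean = 700, sd = 200 / sqrt(2)), tolerance = 1e-12)
  expect_equal(fp_features(42)[["sd"]], 0)  # single sample: SD 0 by convention
  expect_error(fp_features(numeric(0)), "empty")
})

test_that("median frequency recovers pure and mixed tones", {
  fs <- 1000
  t <- (0:499) / fs
  bin <- fs / 500
  expect_lt(abs(median_frequency(sin(2 * pi * 50 * t), fs) - 50), bin)
  two_tone <- sin(2 * pi * 40 * t) + sin(2 * pi * 80 * t)
  mf <- median_frequency(two_tone, fs)
  expect_true(mf >= 40 && mf <= 80)
  expect_equal(mf, oracle_median_frequency(two_tone, fs), tolerance = 1e-6)
  expect_equal(median_frequency(rep(0, 100), fs), 0)
  expect_error(median_frequency(1, fs), "at least 2")
})

test_that("median frequency matches the direct cumulative-PSD oracle", {
  set.seed(7)
  fs <- 200
  for (i in 1:50) {
    x <- rnorm(64) + sin(2 * pi * runif(1, 5, 90) * (0:63) / fs)
    expect_lt(abs(median_frequency(x, fs) - oracle_median_frequency(x, fs)),
              fs / 64)  # within one spectral bin
  }
})

test_that("amplitude histogram bins count SD bands and sum to one", {
  expect_equal(histogram_bins(c(-1, 1)), c(H1 = 1, H2 = 0, H3 = 0))
  expect_equal(histogram_bins(rep(3, 10)), c(H1 = 1, H2 = 0, H3 = 0))
  set.seed(3)
  for (i in 1:50) {
    x <- rnorm(50, sd = runif(1, 0.1, 10))
    got <- histogram_bins(x)
    expect_equal(unname(got), oracle_hist_bins(x), tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("feature extraction yields the canonical 44-column layout", {
  spec <- canonical_feature_spec()
  expect_equal(nrow(spec), 44)
  expect_equal(unname(table(spec$family)[c("ACC", "FPM", "FPSD", "MF", "H1", "H2", "H3")]),
               c(8L, 2L, 2L, 8L, 8L, 8L, 8L), ignore_attr = TRUE)

  s <- tiny_session(seed = 4, duration_per = 5)  # 20 s trial
  fm <- extract_features(s)
  expect_equal(length(feature_cols(fm)), 44)
  expect_equal(nrow(fm), floor((20 - 0.5) / 0.2 + 1e-9) + 1)
  expect_false(any(is.na(fm)))
  # H bins sum to one for every window and channel
  h1 <- as.matrix(fm[grep("^h1_", names(fm))])
  h2 <- as.matrix(fm[grep("^h2_", names(fm))])
  h3 <- as.matrix(fm[grep("^h3_", names(fm))])
  expect_true(all(abs(h1 + h2 + h3 - 1) < 1e-12))
})

test_that("feature counts obey the sensor-conservation formula", {
  s <- tiny_session(seed = 4, duration_per = 2)
  cases <- sensor_cases()
  for (i in seq_len(nrow(cases))) {
    spec <- case_feature_spec(cases[i, ])
    # each retained sEMG channel contributes MF + 3 histogram bins; ACC and
    # force-plate features are counted per channel
    n_semg <- sum(grepl("^semg", spec$channel_id) & spec$family == "MF")
    n_acc <- sum(spec$family == "ACC")
    n_fp <- sum(spec$family == "FPM")
    expect_equal(nrow(spec), 4 * n_semg + n_acc + 2 * n_fp,
                 label = paste("case", cases$case_id[i]))
    fm <- extract_features(s, spec = spec)
    expect_equal(length(feature_cols(fm)), nrow(spec))
  }
})

test_that("streamed study feature extraction matches the materialized path", {
  profs <- default_profiles()[1]
  fm_stream <- simulate_study_features(profs, n_trials = 2, seed = 3)
  fm_full <- study_features(generate_study(profs, n_trials = 2, seed = 3))
  expect_equal(fm_stream, fm_full)
})

test_that("missing channels in a feature spec raise a configuration error", {
  s <- tiny_session(seed = 4, duration_per = 2)
  spec <- canonical_feature_spec()
  spec$channel_id[1] <- "accel_nonexistent"
  expect_error(extract_features(s, spec = spec), "accel_nonexistent")
})

test_that("z-score normalization learns on training data and is applied frozen", {
  fm <- blob_features(n_trials = 2, per_class = 10, seed = 5)
  train <- fm[fm$trial_id == 1, ]
  test <- fm[fm$trial_id == 2, ]
  nz <- fit_normalizer(train)
  tr_n <- apply_normalizer(train, nz)
  m <- as.matrix(tr_n[feature_cols(tr_n)])
  expect_equal(unname(colMeans(m)), rep(0, ncol(m)), tolerance = 1e-9)
  expect_equal(unname(apply(m, 2, sd)), rep(1, ncol(m)), tolerance = 1e-9)
  te_n <- apply_normalizer(test, nz)
  expect_gt(max(abs(colMeans(as.matrix(te_n[feature_cols(te_n)])))), 1e-3)

  simple <- tibble::tibble(subject_id = "s", trial_id = 1,
                           window_start_s = 1:3, label = factor("walk"),
                           f1 = c(1, 2, 3))
  out <- apply_normalizer(simple, fit_normalizer(simple))
  expect_equal(out$f1, c(-1, 0, 1))

  degenerate <- dplyr::mutate(simple, f1 = 5)
  expect_error(fit_normalizer(degenerate), "f1")
})
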