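test_that("standing with zero noise gives an identically zero speed trace", {
  sch <- fixed_schedule(c("stand", "stand"), duration_per = 5)
  sp <- simulate_speed(sch, tiny_profile(), fs = 100, seed = 1, noise_sd = 0)
  expect_true(all(sp$speed_mps == 0))
})

test_that("speed converges to the preferred speed with first-order lag", {
  prof <- tiny_profile()  # preferred walk = 0.65; build custom 1.3 profile
  prof2 <- subject_profile("s2", 1.4, 2.5,
                           preferred_speeds = c(stand = 0, walk = 1.3,
                                                run = 2.0, sprint = 3.0))
  sch <- fixed_schedule(c("stand", "walk"), duration_per = 15)
  sp <- simulate_speed(sch, prof2, fs = 100, seed = 1, noise_sd = 0.05)
  # after >= 5 time constants (lag 1.5 s) the mean sits at the preferred speed
  steady <- sp$speed_mps[sp$time_s >= 15 + 5 * prof2$response_lag]
  expect_lt(abs(mean(steady) - 1.3), 0.05)
  # steady-state means respect the labelling band of each activity
  expect_true(mean(steady) > 0 && mean(steady) <= prof2$walk_upper)
})

test_that("speed simulation is bitwise deterministic given the seed", {
  sch <- fixed_schedule(c("walk", "run"), duration_per = 5)
  a <- simulate_speed(sch, tiny_profile(), fs = 300, seed = 7)
  b <- simulate_speed(sch, tiny_profile(), fs = 300, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, simulate_speed(sch, tiny_profile(), fs = 300, seed = 8)))
})

semg_spec <- function(muscle = "gastrocnemius", segment = "shank", fs = 1000) {
  channel_spec(paste0("semg_", muscle, "_left"), "semg", muscle, segment,
               "left", fs)
}

test_that("sEMG RMS tracks the configured per-activity gains", {
  cfg <- session_config()
  prof <- tiny_profile()
  sch <- fixed_schedule(c("stand", "walk", "run"), duration_per = 8)
  sp <- simulate_speed(sch, prof, fs = cfg$fs_speed, seed = 2, noise_sd = 0)
  x <- synthesize_semg(sp, semg_spec(), prof, seed = 3, config = cfg)
  seg_rms <- function(lo, hi) {
    v <- x$value[x$time_s >= lo & x$time_s < hi]
    sqrt(mean(v^2))
  }
  # stand baseline within 10% of the configured gain over >= 5 s
  expect_lt(abs(seg_rms(1, 7) - cfg$semg_gains$shank[["stand"]]),
            0.1 * cfg$semg_gains$shank[["stand"]])
  # running is hotter than walking for a calf muscle
  expect_gt(seg_rms(20, 24), seg_rms(12, 16))
})

test_that("zero-amplitude sEMG configuration yields an all-zero stream", {
  cfg <- session_config(semg_gains = list(
    shank = c(stand = 0, walk = 0, run = 0, sprint = 0),
    thigh = c(stand = 0, walk = 0, run = 0, sprint = 0)
  ))
  sch <- fixed_schedule(c("walk"), duration_per = 5)
  sp <- simulate_speed(sch, tiny_profile(), fs = 300, seed = 1, noise_sd = 0)
  x <- synthesize_semg(sp, semg_spec(), tiny_profile(), seed = 1, config = cfg)
  expect_true(all(x$value == 0))
})

test_that("signal generators reject mismatched channel modalities", {
  sch <- fixed_schedule("walk", duration_per = 2)
  sp <- simulate_speed(sch, tiny_profile(), fs = 300, seed = 1)
  acc <- channel_spec("accel_x", "accel", "gastrocnemius", "shank", "left", 100)
  expect_error(synthesize_semg(sp, acc, tiny_profile()), "sEMG")
  expect_error(synthesize_accelerometer(sp, semg_spec(), tiny_profile()),
               "accelerometer")
})

test_that("standing accelerometer with zero noise reads exactly 1 g", {
  cfg <- session_config(accel_noise_sd = 0)
  sch <- fixed_schedule(c("stand"), duration_per = 5)
  sp <- simulate_speed(sch, tiny_profile(), fs = 300, seed = 1, noise_sd = 0)
  acc <- channel_spec("a", "accel", "gastrocnemius", "shank", "left", 100)
  x <- synthesize_accelerometer(sp, acc, tiny_profile(), seed = 1, config = cfg)
  expect_equal(sqrt(x$x^2 + x$y^2 + x$z^2), rep(1, nrow(x)), tolerance = 1e-12)
})

test_that("shank accelerations exceed thigh accelerations at equal speed", {
  cfg <- session_config(accel_noise_sd = 0)
  expect_gt(cfg$accel_amp_per_speed[["shank"]], cfg$accel_amp_per_speed[["thigh"]])
  sch <- fixed_schedule(c("run"), duration_per = 10)
  sp <- simulate_speed(sch, tiny_profile(), fs = 300, seed = 1, noise_sd = 0)
  shank <- channel_spec("a1", "accel", "tibialis_anterior", "shank", "left", 100)
  thigh <- channel_spec("a2", "accel", "vastus_medialis", "thigh", "left", 100)
  xs <- synthesize_accelerometer(sp, shank, tiny_profile(), seed = 1, config = cfg)
  xt <- synthesize_accelerometer(sp, thigh, tiny_profile(), seed = 1, config = cfg)
  norm_sd <- function(x) sd(sqrt(x$x^2 + x$y^2 + x$z^2))
  expect_gt(norm_sd(xs), norm_sd(xt))
})

test_that("mean windowed accelerometer norm does not decrease with speed", {
  cfg <- session_config(accel_noise_sd = 0)
  prof <- subject_profile("s", 1.4, 2.5,
                          preferred_speeds = c(stand = 0, walk = 1.0,
                                               run = 2.0, sprint = 3.0))
  acc <- channel_spec("a", "accel", "tibialis_anterior", "shank", "left", 100)
  mean_norm_at <- function(act) {
    sch <- fixed_schedule(c(act), duration_per = 10)
    sp <- simulate_speed(sch, prof, fs = 300, seed = 1, noise_sd = 0)
    x <- synthesize_accelerometer(sp, acc, prof, seed = 1, config = cfg)
    mean(sqrt(x$x^2 + x$y^2 + x$z^2))
  }
  expect_gte(mean_norm_at("run"), mean_norm_at("walk"))
})

test_that("force plates split weight evenly while standing (no sway)", {
  cfg <- session_config(fp_sway_sd = 0, fp_noise_sd = 0)
  sch <- fixed_schedule(c("stand"), duration_per = 5)
  sp <- simulate_speed(sch, tiny_profile(), fs = 300, seed = 1, noise_sd = 0)
  fp <- synthesize_force_plates(sp, tiny_profile(), seed = 1, config = cfg)
  w <- cfg$body_mass_kg * 9.81
  expect_equal(fp$left_n, rep(w / 2, nrow(fp)))
  expect_true(all(fp$left_n - fp$right_n == 0))
})

test_that("walking shows double support and running shows flight phases", {
  cfg <- session_config()
  prof <- tiny_profile()
  sch <- fixed_schedule(c("walk", "run"), duration_per = 10)
  sp <- simulate_speed(sch, prof, fs = 300, seed = 2, noise_sd = 0)
  fp <- synthesize_force_plates(sp, prof, seed = 2, config = cfg)
  walk_seg <- fp[fp$time_s >= 4 & fp$time_s < 10, ]
  run_seg <- fp[fp$time_s >= 14 & fp$time_s < 20, ]
  expect_true(any(walk_seg$left_n > 0 & walk_seg$right_n > 0))
  expect_true(any(run_seg$left_n == 0 & run_seg$right_n == 0))
  expect_true(all(fp$left_n >= 0 & fp$right_n >= 0))
})

test_that("stance impulse balances body weight within 10%", {
  cfg <- session_config()
  prof <- tiny_profile()
  for (act in c("walk", "run")) {
    sch <- fixed_schedule(c(act), duration_per = 20)
    sp <- simulate_speed(sch, prof, fs = 300, seed = 3, noise_sd = 0)
    fp <- synthesize_force_plates(sp, prof, seed = 3, config = cfg)
    sel <- fp$time_s >= 5  # steady gait, whole strides dominate
    total <- mean(fp$left_n[sel] + fp$right_n[sel])
    w <- cfg$body_mass_kg * 9.81
    expect_lt(abs(total - w), 0.1 * w)
  }
})

test_that("cross-plate strikes swap stance assignment between plates", {
  prof <- tiny_profile()
  sch <- fixed_schedule(c("run"), duration_per = 10)
  sp <- simulate_speed(sch, prof, fs = 300, seed = 4, noise_sd = 0)
  base <- synthesize_force_plates(sp, prof, seed = 4,
                                  config = session_config(cross_strike_fraction = 0))
  default <- synthesize_force_plates(sp, prof, seed = 4, config = session_config())
  expect_identical(base, default)
  swapped <- synthesize_force_plates(sp, prof, seed = 4,
                                     config = session_config(cross_strike_fraction = 1))
  expect_equal(swapped$left_n, base$right_n)
  expect_equal(swapped$right_n, base$left_n)
})

test_that("a full session has the complete 19-channel layout and is reproducible", {
  s <- tiny_session(seed = 5, duration_per = 2)
  counts <- table(s$channels$modality)
  expect_equal(unname(counts[c("semg", "accel", "force_plate", "speed")]),
               c(8L, 8L, 2L, 1L), ignore_attr = TRUE)
  s2 <- tiny_session(seed = 5, duration_per = 2)
  expect_identical(s$channels$data, s2$channels$data)
  # different session seed, same schedule: streams differ, schedule shared
  s3 <- tiny_session(seed = 6, duration_per = 2)
  expect_identical(s$schedule, s3$schedule)
  expect_false(identical(s$channels$data, s3$channels$data))
})
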