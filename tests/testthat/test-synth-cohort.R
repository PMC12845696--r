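waveform_params <- function(dc = c(ax = 0, ay = 0, az = 0,
                                   gx = 0, gy = 0, gz = 0),
                            harmonics = NULL, impact_amplitude = 0,
                            impact_width_phase = 0.05) {
  if (is.null(harmonics))
    harmonics <- stats::setNames(rep(list(numeric(0)), 6),
                                 c("ax", "ay", "az", "gx", "gy", "gz"))
  list(dc = dc, harmonics = harmonics,
       impact_amplitude = impact_amplitude,
       impact_width_phase = impact_width_phase)
}

test_that("stride waveform degenerates to the DC level and is deterministic", {
  grid <- (0:99) / 100
  p <- waveform_params(dc = c(ax = 0, ay = 0, az = 3.5,
                              gx = 0, gy = 0, gz = -1))
  w <- generate_stride_waveform(grid, p)
  expect_equal(unname(w[, "az"]), rep(3.5, 100))
  expect_equal(unname(w[, "gz"]), rep(-1, 100))
  expect_identical(w, generate_stride_waveform(grid, p))

  p$dc[["az"]] <- Inf
  expect_error(generate_stride_waveform(grid, p), "non-finite")
  expect_error(generate_stride_waveform(c(0.5, 0.2), waveform_params()),
               "sorted")
})

test_that("narrowing the impact pulse increases vertical kurtosis", {
  grid <- (0:255) / 256
  kurt_for <- function(width) {
    p <- waveform_params(impact_amplitude = 8, impact_width_phase = width)
    time_domain_features(generate_stride_waveform(grid, p)[, "az"])[["kurt"]]
  }
  expect_gt(kurt_for(0.02), kurt_for(0.04))
})

test_that("noise-free recordings are exactly periodic with n+1 boundaries", {
  cfg <- synth_config(n_participants = 1, strides_per_condition = 5,
                      timing_jitter_sd = 0, amplitude_jitter_sd = 0,
                      amplitude_drift_sd = 0,
                      noise_sd = c(ax = 0, ay = 0, az = 0,
                                   gx = 0, gy = 0, gz = 0))
  set.seed(1)
  out <- generate_recording(cfg, "P01", 0, 1.3, "NF", 5)
  gt <- out$ground_truth
  expect_equal(nrow(gt), 6)  # n_strides + 1 window boundaries
  expect_true(all(diff(gt$event_index) == diff(gt$event_index)[1]))
  # first two stride blocks are identical sample-for-sample
  period <- diff(gt$event_index)[1]
  b1 <- out$recording$data$az[seq_len(period)]
  b2 <- out$recording$data$az[period + seq_len(period)]
  expect_equal(b1, b2)
  expect_error(generate_recording(cfg, "P01", 0, 1.3, "NF", 1), ">= 2")
})

test_that("the fatigued vertical-channel mean drops by the configured delta", {
  diffs <- vapply(1:3, function(seed) {
    cfg <- synth_config(n_participants = 1, strides_per_condition = 60,
                        seed = seed)
    set.seed(seed)
    nf <- generate_recording(cfg, "P01", 0, 1.3, "NF", 60)
    f <- generate_recording(cfg, "P01", 0, 1.3, "F", 60)
    mean(f$recording$data$az) - mean(nf$recording$data$az)
  }, numeric(1))
  expect_equal(mean(diffs), -0.8, tolerance = 0.05)
})

test_that("cohorts are bit-identical under a fixed seed and config", {
  cfg <- synth_config(n_participants = 2, strides_per_condition = 8, seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_equal(length(c1$recordings), 4)  # one NF and one F per participant
  expect_setequal(vapply(c1$recordings, `[[`, "", "condition"),
                  c("NF", "F"))
  # ground-truth event times strictly increasing within each recording
  for (key in names(c1$recordings)) {
    gt <- c1$ground_truth[paste(c1$ground_truth$participant,
                                c1$ground_truth$condition, sep = "_") == key, ]
    expect_true(all(diff(gt$event_time) > 0))
  }
})

test_that("each fatigue effect moves its matching feature in the stated direction", {
  directions <- c(acc_z_mean = -1, acc_y_max = 1, acc_mag_kurt = 1,
                  gyro_y_rms = 1, acc_z_sampen = 1)
  for (seed in 1:5) {
    ft <- cohort_feature_table(list(n_participants = 4,
                                    strides_per_condition = 25, seed = seed),
                               extended = TRUE)
    for (feat in names(directions)) {
      delta <- mean(ft[[feat]][ft$condition == 1]) -
        mean(ft[[feat]][ft$condition == 0])
      expect_gt(delta * directions[[feat]], 0,
                label = sprintf("seed %d, %s direction", seed, feat))
    }
  }
})

test_that("the cohort random-intercept variance is recovered downstream", {
  ft <- cohort_feature_table(list(n_participants = 20,
                                  strides_per_condition = 25,
                                  random_intercept_sd = 2, seed = 5))
  fit <- fit_random_intercept_model(ft, "acc_z_mean")
  expect_gt(fit$sigma_u2, 2)   # within a factor of 2 of the true 4.0
  expect_lt(fit$sigma_u2, 8)
})

test_that("a null cohort yields no spurious fatigue effect", {
  null_effects <- list(delta_vertical_mean = 0, delta_lateral_peak = 0,
                       impact_sharpen_factor = 1, noise_inflation = 1,
                       jitter_inflation = 1)
  zs <- vapply(1:6, function(seed) {
    ft <- cohort_feature_table(list(n_participants = 4,
                                    strides_per_condition = 20,
                                    fatigue_effects = null_effects,
                                    seed = seed))
    fit_random_intercept_model(ft, "acc_z_mean")$z
  }, numeric(1))
  expect_gte(mean(abs(zs) < 3), 5 / 6)
})
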