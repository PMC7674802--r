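test_that("noise-free gaze reproduces its own truth through the detector", {
  set.seed(31)
  scene <- generate_scene("few", "high")
  bp <- behavior_params(jitter_sd_px = 0)
  sim <- simulate_gaze(scene, bp, n_fix = 10)
  det <- detect_fixations(sim$gaze)
  expect_identical(nrow(det), nrow(sim$truth))
  expect_equal(det$onset, sim$truth$onset)
  expect_equal(det$offset, sim$truth$offset)
  expect_identical(det$n_frames, sim$truth$n_frames)
  expect_equal(det$x, sim$truth$x)
  expect_equal(det$y, sim$truth$y)
})

test_that("within-fixation samples stay inside the dispersion circle", {
  set.seed(32)
  scene <- generate_scene("many", "low")
  sim <- simulate_gaze(scene, n_fix = 20)
  g <- sim$gaze[sim$gaze$eye == "R", ]
  for (i in seq_len(nrow(sim$truth))) {
    fx <- sim$truth[i, ]
    s <- g[g$t_sec >= fx$onset - 1e-9 & g$t_sec < fx$offset - 1 / 120, ]
    expect_gte(nrow(s), 6)
    d <- sqrt((s$x_px - mean(s$x_px))^2 + (s$y_px - mean(s$y_px))^2)
    expect_true(all(d <= 40))
  }
  # consecutive fixations are separated by a > 80 px jump
  jumps <- sqrt(diff(sim$truth$x)^2 + diff(sim$truth$y)^2)
  expect_true(all(jumps > 80))
})

test_that("behavioral condition effects hold in expectation", {
  set.seed(33)
  bp <- behavior_params()
  # object count drives the number of fixations
  n_few <- replicate(300, {
    max(4, rpois(1, bp$n_fix_mean[["few"]]))
  })
  n_many <- replicate(300, {
    max(4, rpois(1, bp$n_fix_mean[["many"]]))
  })
  expect_gt(mean(n_many), mean(n_few))

  # color similarity drives target-panel revisits
  sc_high <- generate_scene("few", "high")
  sc_low <- generate_scene("few", "low")
  rev_high <- mean(replicate(60, {
    mean(simulate_gaze(sc_high, bp, n_fix = 12)$truth$panel == "target")
  }))
  rev_low <- mean(replicate(60, {
    mean(simulate_gaze(sc_low, bp, n_fix = 12)$truth$panel == "target")
  }))
  expect_gt(rev_high, rev_low)
})

test_that("EEG simulation is deterministic and places the P100 at Oz", {
  truth <- data.frame(onset = 1, n_objects = 1, n_colors = 1,
                      on_target = FALSE, keypress = FALSE,
                      keypress_time = NA)
  np0 <- neural_params(noise_pink_uv = 0, noise_white_uv = 0,
                       amp_jitter_sd = 0, blink_rate = 0)
  eeg <- simulate_eeg(truth, np0, duration = 2.5)
  oz <- eeg$data["Oz", ]
  peak_t <- (which.max(oz) - 1) / eeg$fs
  expect_lt(abs(peak_t - (1 + 0.095)), 1 / eeg$fs)
  # Oz carries the maximal deflection among EEG channels
  expect_identical(names(which.max(apply(eeg$data, 1, max))), "Oz")
  # amplitude = base + per-object + per-color gains
  np <- neural_params()
  expected <- np$p100_base_amp + np$gain_per_object + np$gain_per_color
  # sampling-grid offset from the Gaussian center costs < 1%
  expect_equal(max(oz), expected, tolerance = 0.01)

  set.seed(34); a <- simulate_eeg(truth, neural_params(), duration = 2.5)
  set.seed(34); b <- simulate_eeg(truth, neural_params(), duration = 2.5)
  expect_identical(a$data, b$data)
})

test_that("keypress fixations carry more relative delta power", {
  set.seed(35)
  onsets <- seq(1, 39, by = 2)
  kp <- rep(c(TRUE, FALSE), length.out = length(onsets))
  truth <- data.frame(onset = onsets, n_objects = 1, n_colors = 1,
                      on_target = FALSE, keypress = kp,
                      keypress_time = ifelse(kp, onsets + 0.25, NA))
  eeg <- simulate_eeg(truth, neural_params(), duration = 41)
  fx <- data.frame(onset = onsets, offset = onsets + 0.5)
  feats <- bandpower_features(eeg, fx, kp)
  expect_gt(mean(feats$rel_delta[feats$has_keypress]),
            mean(feats$rel_delta[!feats$has_keypress]))
})

test_that("the keypress-duration option lengthens action fixations", {
  set.seed(38)
  bp <- behavior_params(keypress_extra_ms = 150)
  truth <- do.call(rbind, lapply(1:12, function(i) {
    simulate_gaze(generate_scene("few", "high"), bp)$truth
  }))
  ds <- duration_stats(truth$duration * 1000, truth$keypress)
  expect_gt(ds$median_action, ds$median_nonaction)
  expect_lt(ds$p_value, 0.01)
})

test_that("clock-error injection applies the exact affine map", {
  set.seed(36)
  s <- simulate_session(n_per_condition = 1, clock_offset = 0,
                        clock_drift = 1, n_fix_per_scene = 4)
  t_ref <- s$gaze$t_sec
  expect_identical(s$clock$offset, 0)

  shifted <- inject_clock_error(s, 0.5, 1)
  expect_equal(shifted$gaze$t_sec, t_ref + 0.5)

  aff <- inject_clock_error(s, 0.2, 1.001)
  expect_equal(aff$gaze$t_sec, 0.2 + 1.001 * t_ref)
  expect_equal(aff$clock$offset, 0.2)
  expect_equal(aff$clock$drift, 1.001)
})

test_that("sessions are reproducible under a fixed seed", {
  set.seed(37); a <- simulate_session(n_per_condition = 1, n_fix_per_scene = 4)
  set.seed(37); b <- simulate_session(n_per_condition = 1, n_fix_per_scene = 4)
  expect_identical(a$gaze, b$gaze)
  expect_identical(a$eeg$data, b$eeg$data)
  expect_identical(a$truth, b$truth)
})
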