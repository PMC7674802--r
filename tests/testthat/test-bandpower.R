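test_that("a pure theta tone is theta-dominant", {
  fs <- 256
  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  bp <- relative_bandpower(sin(2 * pi * 6 * t), fs = fs)
  expect_gt(bp[["theta"]], 0.9)
  expect_equal(sum(bp), 1, tolerance = 1e-9)
  expect_true(all(bp >= 0))
})

test_that("two-tone segments split power by the analytic energy ratio", {
  fs <- 256
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  # theta tone at amplitude 1, alpha1 tone at amplitude 2: energies 1:4
  x <- sin(2 * pi * 6 * t) + 2 * sin(2 * pi * 9 * t)
  bp <- relative_bandpower(x, fs = fs)
  expect_equal(bp[["theta"]], 0.2, tolerance = 0.05 * 5)
  expect_equal(bp[["alpha1"]], 0.8, tolerance = 0.05 * 5)
})

test_that("white-noise fractions approach the bandwidth ratios", {
  fs <- 256
  set.seed(111)
  acc <- rowMeans(replicate(100, {
    relative_bandpower(rnorm(4 * fs), fs = fs)
  }))
  widths <- vapply(eeg_bands(), diff, 0)
  expect_equal(unname(acc), unname(widths / sum(widths)), tolerance = 0.05)
  expect_equal(acc[["beta"]], 17 / 29.5, tolerance = 0.05)
})

test_that("segment extraction follows the half-open sample rule", {
  eeg <- structure(list(fs = 256, channels = default_montage(),
                        data = matrix(rnorm(20 * 2560), 20,
                                      dimnames = list(default_montage(),
                                                      NULL)),
                        t0 = 0, units = "uV"), class = "eeg_record")
  seg <- extract_segment(eeg, data.frame(onset = 2.0, offset = 2.4))
  # [ceil(2.0*256), ceil(2.4*256)) = [512, 615) -> 103 samples
  expect_identical(ncol(seg$data), 103L)
  # fixation straddling the end of the recording is rejected
  expect_null(extract_segment(eeg, data.frame(onset = 9.9, offset = 10.2)))
  expect_null(extract_segment(eeg, data.frame(onset = -0.1, offset = 0.2)))
})

test_that("an all-zero segment has undefined bandpower", {
  expect_error(relative_bandpower(rep(0, 256), fs = 256), "all-zero")
})

test_that("action classification is above chance with the default generator", {
  set.seed(112)
  onsets <- seq(1, 120, by = 1.5)
  kp <- rep(c(TRUE, FALSE), length.out = length(onsets))
  truth <- data.frame(onset = onsets, n_objects = 1, n_colors = 1,
                      on_target = FALSE, keypress = kp,
                      keypress_time = ifelse(kp, onsets + 0.25, NA))
  eeg <- simulate_eeg(truth, neural_params(), duration = 122)
  fx <- data.frame(onset = onsets, offset = onsets + 0.5)
  feats <- bandpower_features(eeg, fx, kp)
  cv <- classify_action_fixations(feats)
  expect_gt(cv$mean_accuracy, 0.7)

  # null generator: no keypress-locked component -> chance
  truth0 <- truth; truth0$keypress_time <- NA; truth0$keypress <- FALSE
  eeg0 <- simulate_eeg(truth0, neural_params(), duration = 122)
  feats0 <- bandpower_features(eeg0, fx, kp)
  cv0 <- classify_action_fixations(feats0)
  se <- sqrt(0.25 / cv0$n_used)
  expect_lt(abs(cv0$mean_accuracy - 0.5), 3 * se)
})

test_that("duration distributions separate and stay normalized", {
  set.seed(113)
  dur <- c(rgamma(80, 3, scale = 75) + 250, rgamma(200, 3, scale = 75) + 100)
  kp <- rep(c(TRUE, FALSE), c(80, 200))
  ds <- duration_stats(dur, kp)
  expect_gt(ds$median_action, ds$median_nonaction)
  expect_lt(ds$p_value, 0.01)
  expect_equal(sum(ds$density_action), 1, tolerance = 1e-12)
  expect_equal(sum(ds$density_nonaction), 1, tolerance = 1e-12)
  expect_gte(ds$overlap, 0); expect_lte(ds$overlap, 1)

  # identical distributions: mostly non-significant under the null
  p <- replicate(60, {
    d <- rgamma(60, 3, scale = 75) + 100
    duration_stats(d, rep(c(TRUE, FALSE), 30))$p_value
  })
  expect_lt(mean(p < 0.05), 0.2)
})
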