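# shared clean template fixture built once per file
make_template <- function(seed = 101) {
  set.seed(seed)
  onsets <- seq(1, 60, by = 1.1)
  truth <- data.frame(onset = onsets, n_objects = 2, n_colors = 1,
                      on_target = FALSE, keypress = FALSE,
                      keypress_time = NA)
  eeg <- simulate_eeg(truth, neural_params(noise_pink_uv = 0,
                                           noise_white_uv = 0,
                                           amp_jitter_sd = 0,
                                           blink_rate = 0),
                      duration = 62)
  ep <- bandpass_epochs(extract_epochs(eeg, onsets))
  build_reference(ep)
}

test_that("regressors are orthonormal and span the jitter directions", {
  tpl <- make_template()
  reg <- build_regressors(tpl)
  G <- crossprod(reg$basis)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-10)
  expect_gte(ncol(reg$basis), 3)

  # no jitter: the single direction reproduces the template
  reg0 <- build_regressors(tpl, k = 3, lat_jitter_ms = 0, width_jitter = 0)
  expect_gt(abs(cor(reg0$basis[, 1], tpl$waveform)), 0.9999)
  expect_gt(reg0$sdev[1]^2 / sum(reg0$sdev^2), 0.99)

  # latency jitter only: a component tracks the temporal derivative
  regL <- build_regressors(tpl, k = 2, lat_jitter_ms = 20, width_jitter = 0)
  deriv <- c(0, diff(tpl$waveform))
  expect_gt(abs(cor(regL$basis[, 2], deriv)), 0.8)
})

test_that("an exact template epoch is recovered with unit fit", {
  tpl <- make_template()
  reg <- build_regressors(tpl)
  est <- fit_mlrd(tpl$waveform, reg)
  pk <- which.max(tpl$waveform)
  expect_equal(est$amplitude, max(tpl$waveform), tolerance = 0.05)
  expect_equal(est$latency_ms, (pk - 1 - tpl$pre_samples) / tpl$fs * 1000,
               tolerance = 4)   # one-sample grid tolerance
  expect_gt(est$fit_r2, 0.99)
  expect_false(est$low_confidence)
})

test_that("amplitude and latency recover under noise and shift", {
  tpl <- make_template()
  reg <- build_regressors(tpl)
  n <- tpl$n_samples
  w <- tpl$waveform; peak <- max(w)
  true_lat <- (which.max(w) - 1 - tpl$pre_samples) / tpl$fs * 1000 + 10
  shift <- round(0.010 * tpl$fs)
  set.seed(102)
  est <- t(replicate(150, {
    y <- 2 * c(rep(0, shift), w)[seq_len(n)]
    y <- y + rnorm(n, 0, 2 * peak / 5)      # SNR 5
    e <- fit_mlrd(y, reg)
    c(e$amplitude, e$latency_ms)
  }))
  expect_lt(abs(mean(est[, 1]) / (2 * peak) - 1), 0.10)
  expect_lt(sqrt(mean((est[, 2] - true_lat)^2)), 8)
})

test_that("recovered group means order with the injected gain", {
  tpl <- make_template()
  reg <- build_regressors(tpl)
  n <- tpl$n_samples
  w <- tpl$waveform; peak <- max(w)
  set.seed(103)
  means <- vapply(c(1, 1.5, 2), function(gain) {
    mean(replicate(150, {
      y <- gain * w + rnorm(n, 0, gain * peak / 2)   # SNR 2
      fit_mlrd(y, reg)$amplitude
    }))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("single-epoch amplitudes vary more than group means", {
  tpl <- make_template()
  reg <- build_regressors(tpl)
  n <- tpl$n_samples; w <- tpl$waveform; peak <- max(w)
  set.seed(104)
  single <- replicate(200, fit_mlrd(w + rnorm(n, 0, peak / 2), reg)$amplitude)
  groups <- colMeans(matrix(single, nrow = 20))
  expect_gt(var(single), var(groups))
})

test_that("group comparisons produce the conventional star codes", {
  expect_identical(compare_groups(rep(1, 5), rep(1, 5))$star, "ns")
  expect_equal(compare_groups(rep(1, 5), rep(1, 5))$p, 1)
  set.seed(105)
  a <- rnorm(100); b <- rnorm(100, 1)
  cmp <- compare_groups(a, b)
  expect_identical(cmp$star, "**")
  expect_lt(cmp$p, 0.01)
  # the star code is always consistent with the computed p value
  for (i in 1:20) {
    aa <- rnorm(15); bb <- rnorm(15, runif(1, 0, 1.5))
    cc <- compare_groups(aa, bb)
    expected <- if (cc$p < 0.01) "**" else if (cc$p < 0.05) "*" else "ns"
    expect_identical(cc$star, expected)
  }
  expect_error(compare_groups(1, c(1, 2)), "length")
})
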