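flat_record <- function(dur = 10, fs = 256) {
  structure(list(fs = fs, channels = default_montage(),
                 data = matrix(0, 20, dur * fs,
                               dimnames = list(default_montage(), NULL)),
                 t0 = 0, units = "uV"),
            class = "eeg_record")
}

test_that("epochs span exactly 1 s from 100 ms pre-onset", {
  eeg <- flat_record()
  eeg$data[, ] <- rnorm(length(eeg$data))
  ep <- extract_epochs(eeg, onsets = c(2, 4.5, 7))
  expect_identical(dim(ep$data), c(20L, 256L, 3L))
  expect_identical(ep$pre_samples, 26L)   # 0.1 s at 256 Hz
  expect_identical(ep$n_rejected, 0L)
  # window content matches the raw record (up to baseline subtraction)
  idx <- round((2 - 0.1) * 256) + seq_len(256)
  w <- eeg$data[1, idx]
  expect_equal(ep$data[1, , 1], w - mean(w[1:26]), tolerance = 1e-12)
})

test_that("onsets too close to the recording edges are rejected", {
  eeg <- flat_record(dur = 3)
  ep <- extract_epochs(eeg, onsets = c(0.05, 1.5, 2.5))
  # 0.05 starts before the record; 2.5 runs past the end
  expect_identical(dim(ep$data)[3], 1L)
  expect_identical(ep$n_rejected, 2L)
  expect_warning(extract_epochs(eeg, onsets = 0.01), "no fixation onset")
})

test_that("baseline correction zeroes the pre-onset mean", {
  eeg <- flat_record()
  eeg$data[, ] <- 7.5
  ep <- extract_epochs(eeg, onsets = 3)
  expect_equal(max(abs(ep$data)), 0)
})

test_that("foveal labels follow the content rules", {
  sc <- make_test_scene(rbind(
    test_shape("a", 1000, 500, c(0, 0, 0)),
    test_shape("b", 1040, 520, c(0, 0, 150)),     # D = sqrt(3*150^2) = 260
    test_shape("c", 1500, 900, c(0, 0, 0), is_target = TRUE)
  ))
  events <- list(list(t = 5.2, type = "keypress", scene_id = "test"))

  # fixation over empty background
  l0 <- label_epoch(data.frame(onset = 1, offset = 1.3, x = 600, y = 100),
                    sc, events)
  expect_identical(l0$n_objects, 0L)
  expect_identical(l0$n_colors, 0L)
  expect_false(l0$on_target); expect_false(l0$has_keypress)

  # two foveal shapes with pairwise color distance > 200 -> two colors
  l1 <- label_epoch(data.frame(onset = 1, offset = 1.3, x = 1010, y = 505),
                    sc, events)
  expect_identical(l1$n_objects, 2L)
  expect_identical(l1$n_colors, 2L)
  expect_false(l1$on_target)

  # keypress at fixation midpoint, on a target shape
  l2 <- label_epoch(data.frame(onset = 5.0, offset = 5.4, x = 1500, y = 900),
                    sc, events)
  expect_true(l2$on_target)
  expect_true(l2$has_keypress)

  # similar colors are merged into one group
  sc2 <- make_test_scene(rbind(
    test_shape("a", 1000, 500, c(0, 0, 0)),
    test_shape("b", 1040, 520, c(30, 30, 30))     # D = 90 <= 200
  ))
  l3 <- label_epoch(data.frame(onset = 1, offset = 1.2, x = 1020, y = 510),
                    sc2, events)
  expect_identical(l3$n_colors, 1L)
})

test_that("the epoch bandpass keeps shape and attenuates out-of-band power", {
  eeg <- flat_record()
  t <- (seq_len(ncol(eeg$data)) - 1) / eeg$fs
  eeg$data["Oz", ] <- sin(2 * pi * 5 * t) + sin(2 * pi * 30 * t)
  ep <- extract_epochs(eeg, onsets = c(3, 5, 7), baseline = FALSE)
  out <- bandpass_epochs(ep)
  expect_identical(dim(out$data), dim(ep$data))
  y <- out$data["Oz", , 1]
  p <- Mod(fft(y))^2
  freqs <- (seq_along(p) - 1) * 256 / length(p)
  p5 <- sum(p[freqs > 4 & freqs < 6])
  p30 <- sum(p[freqs > 29 & freqs < 31])
  expect_gt(p5 / p30, 100)
})
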