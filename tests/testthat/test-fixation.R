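test_that("a stationary run yields one fixation with all frames", {
  g <- data.frame(t_sec = (0:9) / 60, x_px = rep(500, 10),
                  y_px = rep(500, 10))
  fx <- detect_fixations(g)
  expect_identical(nrow(fx), 1L)
  expect_identical(fx$n_frames, 10L)
  expect_equal(fx$x, 500)
  expect_equal(fx$duration, 10 / 60)
})

test_that("rapid alternation between distant points yields no fixation", {
  g <- data.frame(t_sec = (0:19) / 60,
                  x_px = rep(c(100, 100, 600, 600), 5),
                  y_px = rep(500, 20))
  expect_identical(nrow(detect_fixations(g)), 0L)
})

test_that("planted fixations separated by large jumps are recovered exactly", {
  set.seed(51)
  centers <- rbind(c(300, 300), c(800, 500), c(1400, 800))
  parts <- lapply(1:3, function(i) {
    n <- 8 + i
    cbind(centers[i, 1] + runif(n, -10, 10),
          centers[i, 2] + runif(n, -10, 10))
  })
  xy <- do.call(rbind, parts)
  g <- data.frame(t_sec = (seq_len(nrow(xy)) - 1) / 60,
                  x_px = xy[, 1], y_px = xy[, 2])
  fx <- detect_fixations(g)
  expect_identical(nrow(fx), 3L)
  expect_identical(fx$n_frames, c(9L, 10L, 11L))
  orc <- oracle_fixations(g)
  expect_equal(fx$onset, orc$onset)
  expect_equal(fx$offset, orc$offset)
  expect_equal(fx$x, orc$x)
})

test_that("the detector matches the brute-force oracle on random traces", {
  set.seed(52)
  for (trial in 1:40) {
    g <- random_trace(n = sample(100:600, 1))
    fx <- detect_fixations(g)
    orc <- oracle_fixations(g)
    if (is.null(orc)) {
      expect_identical(nrow(fx), 0L)
    } else {
      expect_identical(nrow(fx), nrow(orc))
      expect_equal(fx$onset, orc$onset)
      expect_equal(fx$offset, orc$offset)
      expect_identical(fx$n_frames, orc$n_frames)
      expect_equal(fx$x, orc$x)
      expect_equal(fx$y, orc$y)
    }
  }
})

test_that("every detected fixation satisfies the duration and frame minima", {
  set.seed(53)
  g <- random_trace(1000)
  fx <- detect_fixations(g)
  expect_gt(nrow(fx), 0)
  expect_true(all(fx$duration >= 0.100 - 1e-9))
  expect_true(all(fx$n_frames >= 6))
  expect_true(all(fx$offset > fx$onset))
  # non-overlapping and ordered (allow float rounding of the frame grid)
  expect_true(all(diff(fx$onset) > 0))
  expect_true(all(fx$onset[-1] - fx$offset[-nrow(fx)] > -1e-9))
})

test_that("invalid samples and the non-dominant eye are excluded", {
  g <- data.frame(t_sec = rep((0:9) / 60, each = 2),
                  eye = rep(c("L", "R"), 10),
                  x_px = rep(c(100, 500), 10),
                  y_px = 500, valid = TRUE)
  fx <- detect_fixations(g, eye = "R")
  expect_identical(nrow(fx), 1L)
  expect_equal(fx$x, 500)
  idx <- which(g$eye == "R")[1:4]
  g$valid[idx] <- FALSE
  expect_identical(detect_fixations(g, eye = "R")$n_frames, 6L)
})

test_that("empty and unordered streams are handled", {
  expect_identical(nrow(detect_fixations(data.frame(
    t_sec = numeric(0), x_px = numeric(0), y_px = numeric(0)))), 0L)
  g <- data.frame(t_sec = c(0.2, 0.1), x_px = 1, y_px = 1)
  expect_error(detect_fixations(g), "strictly increasing")
})
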