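# Independent oracles used across the suite.

# Brute-force dispersion fixation oracle: for every candidate window it
# re-evaluates the acceptance conditions directly (no incremental state),
# then emits maximal qualifying non-overlapping runs left to right.
oracle_fixations <- function(g, diameter = 80, min_frames = 6,
                             break_jump = 80, min_duration = 0.100) {
  radius <- diameter / 2
  n <- nrow(g)
  frame_period <- stats::median(diff(g$t_sec))
  # window [i..j] is valid iff every step satisfies the jump rule and every
  # sample after the first lies within `radius` of the centroid of the
  # samples before it
  window_valid <- function(i, j) {
    if (j == i) return(TRUE)
    for (m in (i + 1):j) {
      if (sqrt((g$x_px[m] - g$x_px[m - 1])^2 +
               (g$y_px[m] - g$y_px[m - 1])^2) > break_jump) return(FALSE)
      cx <- mean(g$x_px[i:(m - 1)]); cy <- mean(g$y_px[i:(m - 1)])
      if (sqrt((g$x_px[m] - cx)^2 + (g$y_px[m] - cy)^2) > radius) {
        return(FALSE)
      }
    }
    TRUE
  }
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && window_valid(i, j + 1L)) j <- j + 1L
    len <- j - i + 1L
    dur <- g$t_sec[j] - g$t_sec[i] + frame_period
    if (len >= min_frames && dur >= min_duration - 1e-9) {
      out[[length(out) + 1L]] <- data.frame(
        onset = g$t_sec[i], offset = g$t_sec[j] + frame_period,
        x = mean(g$x_px[i:j]), y = mean(g$y_px[i:j]),
        n_frames = len)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# random gaze trace mixing dwell periods and jumps
random_trace <- function(n, fs = 60, dwell_scale = 8, jump_px = 300,
                         jitter = 15) {
  x <- numeric(n); y <- numeric(n)
  i <- 1
  cx <- runif(1, 0, 1920); cy <- runif(1, 0, 1080)
  while (i <= n) {
    len <- min(n - i + 1, 1 + rpois(1, dwell_scale))
    x[i:(i + len - 1)] <- cx + runif(len, -jitter, jitter)
    y[i:(i + len - 1)] <- cy + runif(len, -jitter, jitter)
    i <- i + len
    cx <- cx + sample(c(-1, 1), 1) * runif(1, 80, jump_px)
    cy <- cy + sample(c(-1, 1), 1) * runif(1, 80, jump_px)
  }
  data.frame(t_sec = (seq_len(n) - 1) / fs, x_px = x, y_px = y)
}

# closed-form two-class Fisher discriminant: w = Sw^-1 (mu1 - mu2),
# classify by the midpoint of the projected class means
fisher_two_class <- function(x, y, eps = 1e-6) {
  y <- factor(y)
  x1 <- x[y == levels(y)[1], , drop = FALSE]
  x2 <- x[y == levels(y)[2], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  Sw <- crossprod(sweep(x1, 2, m1)) + crossprod(sweep(x2, 2, m2)) +
    eps * diag(ncol(x))
  w <- solve(Sw, m1 - m2)
  thr <- sum(w * (m1 + m2)) / 2
  function(newx) {
    z <- as.matrix(newx) %*% w
    factor(ifelse(z >= thr, levels(y)[1], levels(y)[2]), levels = levels(y))
  }
}

# minimal hand-built scene for labeling tests
make_test_scene <- function(shapes, screen = frptools:::default_screen()) {
  structure(list(
    scene_id = "test", object_count = "few", color_similarity = "high",
    target_shapes = shapes[0, , drop = FALSE],
    search_shapes = shapes, missing_target = FALSE, screen = screen
  ), class = "frp_scene")
}

test_shape <- function(id, x, y, color, is_target = FALSE) {
  data.frame(shape_id = id, kind = "circle", r = color[1], g = color[2],
             b = color[3], x = x, y = y, bbox_size = 60, rotation = 0,
             is_target = is_target, stringsAsFactors = FALSE)
}

# sinusoid record helper for filter tests
tone_record <- function(freq, fs = 256, dur = 8, channels = "Oz") {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  data <- matrix(rep(sin(2 * pi * freq * t), length(channels)),
                 nrow = length(channels), byrow = TRUE,
                 dimnames = list(channels, NULL))
  structure(list(fs = fs, channels = channels, data = data, t0 = 0,
                 units = "uV"), class = "eeg_record")
}

# steady-state RMS of the central half of a signal (skips filter edges)
central_rms <- function(x) {
  n <- length(x)
  sqrt(mean(x[(n %/% 4):(3 * n %/% 4)]^2))
}
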