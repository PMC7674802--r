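#' Dispersion-based fixation detection
#'
#' Detects fixations as runs of gaze samples confined to a circular region
#' of `dispersion_diameter` px (default 80 px, approximating a 5-degree
#' eye-rotation area at the study's viewing distance). The circle is
#' anchored on the first sample of a candidate run and re-centered on the
#' running centroid after each accepted sample. A fixation is considered
#' over once the gaze jumps further than `break_jump` px from the previous
#' sample. Runs must span at least `min_frames` samples (default 6, i.e.
#' 100 ms at 60 Hz) to qualify.
#'
#' A fixation's `offset` is the last member sample's time plus one frame
#' period, so `duration = n_frames / fs_et` and 6 frames at 60 Hz are
#' exactly 100 ms.
#'
#' @param gaze gaze table (columns `t_sec`, `x_px`, `y_px`, optionally
#'   `eye` and `valid`). If an `eye` column is present only `eye` samples
#'   are used; invalid samples are dropped first.
#' @param dispersion_diameter dispersion circle diameter (px).
#' @param min_frames minimum run length in samples.
#' @param break_jump sample-to-sample jump (px) that ends a fixation.
#' @param min_duration minimum duration (s).
#' @param eye which eye stream to use when `gaze$eye` exists (dominant eye).
#' @return data.frame with one row per fixation: `onset`, `offset`, `x`,
#'   `y` (centroid), `duration`, `n_frames`, `first_idx`, `last_idx`
#'   (indices into the selected sample stream).
#' @export
detect_fixations <- function(gaze, dispersion_diameter = 80, min_frames = 6,
                             break_jump = 80, min_duration = 0.100,
                             eye = "R") {
  g <- select_eye(gaze, eye)
  n <- nrow(g)
  if (n == 0) return(empty_fixations())
  if (is.unsorted(g$t_sec, strictly = TRUE)) {
    stop("gaze timestamps must be strictly increasing within one eye",
         call. = FALSE)
  }
  radius <- dispersion_diameter / 2
  frame_period <- stats::median(diff(g$t_sec))
  if (!is.finite(frame_period)) frame_period <- 1 / 60

  out <- list()
  i <- 1L
  while (i <= n) {
    j <- grow_run(g$x_px, g$y_px, i, n, radius, break_jump)
    len <- j - i + 1L
    dur <- g$t_sec[j] - g$t_sec[i] + frame_period
    # small tolerance: n/fs sums are not exactly representable in binary
    if (len >= min_frames && dur >= min_duration - 1e-9) {
      out[[length(out) + 1L]] <- data.frame(
        onset = g$t_sec[i], offset = g$t_sec[j] + frame_period,
        x = mean(g$x_px[i:j]), y = mean(g$y_px[i:j]),
        duration = dur, n_frames = len, first_idx = i, last_idx = j
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) return(empty_fixations())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# extend a run from start index `i` as far as the incremental dispersion
# and jump criteria allow; returns the last accepted index
grow_run <- function(x, y, i, n, radius, break_jump) {
  cx <- x[i]; cy <- y[i]; len <- 1L
  j <- i
  while (j < n) {
    k <- j + 1L
    jump <- sqrt((x[k] - x[j])^2 + (y[k] - y[j])^2)
    if (jump > break_jump) break
    if (sqrt((x[k] - cx)^2 + (y[k] - cy)^2) > radius) break
    len <- len + 1L
    cx <- cx + (x[k] - cx) / len   # re-center on the running centroid
    cy <- cy + (y[k] - cy) / len
    j <- k
  }
  j
}

select_eye <- function(gaze, eye) {
  g <- gaze
  if (!is.null(g$eye)) g <- g[g$eye == eye, , drop = FALSE]
  if (!is.null(g$valid)) g <- g[as.logical(g$valid), , drop = FALSE]
  g <- g[, intersect(c("t_sec", "x_px", "y_px"), names(g)), drop = FALSE]
  rownames(g) <- NULL
  g
}

empty_fixations <- function() {
  data.frame(onset = numeric(0), offset = numeric(0), x = numeric(0),
             y = numeric(0), duration = numeric(0), n_frames = integer(0),
             first_idx = integer(0), last_idx = integer(0))
}
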