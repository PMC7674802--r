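#' Extract fixation-locked epochs
#'
#' Cuts the continuous record into 1 s windows starting 100 ms before each
#' fixation onset (default window −0.1 s to +0.9 s, 256 samples at 256 Hz).
#' Each epoch is baseline-corrected by subtracting the per-channel mean of
#' the pre-onset interval. Onsets whose window is not fully inside the
#' recording are rejected and counted.
#'
#' @param eeg an `eeg_record` (already resynchronized with the gaze clock).
#' @param onsets fixation-onset times (s, session clock).
#' @param window epoch window relative to onset (s).
#' @param baseline subtract the mean of the pre-onset interval per channel.
#' @return object of class `"frp_epochs"`: `data` (channels x samples x
#'   epochs array), `onsets`, `fs`, `channels`, `window`, `pre_samples`,
#'   `n_rejected`, and a `labels` data.frame slot (filled by
#'   [label_epochs()]).
#' @export
extract_epochs <- function(eeg, onsets, window = c(-0.1, 0.9),
                           baseline = TRUE) {
  stopifnot(inherits(eeg, "eeg_record"), window[2] > window[1])
  fs <- eeg$fs
  n_samp <- as.integer(round((window[2] - window[1]) * fs))
  pre <- as.integer(round(-window[1] * fs))
  n_total <- ncol(eeg$data)

  start_idx <- as.integer(round((onsets + window[1] - eeg$t0) * fs)) + 1L
  ok <- start_idx >= 1L & (start_idx + n_samp - 1L) <= n_total
  kept <- which(ok)
  if (!length(kept)) {
    warning("no fixation onset yields a complete epoch", call. = FALSE)
  }
  data <- array(0, dim = c(nrow(eeg$data), n_samp, length(kept)),
                dimnames = list(eeg$channels, NULL, NULL))
  for (e in seq_along(kept)) {
    idx <- start_idx[kept[e]] + seq_len(n_samp) - 1L
    w <- eeg$data[, idx, drop = FALSE]
    if (baseline && pre > 0) {
      w <- w - rowMeans(w[, seq_len(pre), drop = FALSE])
    }
    data[, , e] <- w
  }
  structure(list(data = data, onsets = onsets[kept], fs = fs,
                 channels = eeg$channels, window = window,
                 pre_samples = pre, n_rejected = sum(!ok),
                 kept_idx = kept, labels = NULL),
            class = "frp_epochs")
}

#' @export
print.frp_epochs <- function(x, ...) {
  cat(sprintf("<frp_epochs> %d epochs x %d channels x %d samples (%d rejected)\n",
              dim(x$data)[3], dim(x$data)[1], dim(x$data)[2], x$n_rejected))
  invisible(x)
}

#' Label a fixation by its foveal content
#'
#' Categorizes one fixation for the amplitude-grouping analysis: the number
#' of shapes and distinct colors inside the foveal region around the
#' fixation centroid (colors differ when their weighted RGB distance
#' exceeds `color_threshold`), whether any foveated shape is a target, and
#' whether a keypress occurred during the fixation.
#'
#' @param fixation one-row fixation record (`onset`, `offset`, `x`, `y`).
#' @param scene the `frp_scene` on display during the fixation.
#' @param events event log: list of `list(t, type, ...)` entries (keypress
#'   events are matched by `t` within the fixation interval).
#' @param fovea_radius foveal radius (px).
#' @param color_threshold color-difference threshold.
#' @return list: `n_objects`, `n_colors`, `on_target`, `has_keypress`.
#' @export
label_epoch <- function(fixation, scene, events, fovea_radius = 80,
                        color_threshold = 200) {
  content <- foveal_content(scene, c(fixation$x, fixation$y),
                            fovea_radius, color_threshold)
  kp_times <- event_times(events, "keypress")
  has_kp <- any(kp_times >= fixation$onset & kp_times <= fixation$offset)
  list(n_objects = content$n_objects, n_colors = content$n_colors,
       on_target = content$on_target, has_keypress = has_kp)
}

event_times <- function(events, type) {
  t <- vapply(events, function(e) if (identical(e$type, type)) e$t else NA_real_,
              0)
  t[!is.na(t)]
}

#' Label every epoch of a set from its fixation and scene
#'
#' @param epochs an `frp_epochs` object.
#' @param fixations fixation table aligned with the epochs' onsets (the
#'   rows indexed by `epochs$kept_idx`), including a `scene_id` column.
#' @param scenes named list of `frp_scene` objects keyed by scene id.
#' @param events event log.
#' @inheritParams label_epoch
#' @return the epochs object with a filled `labels` data.frame.
#' @export
label_epochs <- function(epochs, fixations, scenes, events,
                         fovea_radius = 80, color_threshold = 200) {
  fx <- fixations[epochs$kept_idx, , drop = FALSE]
  labs <- lapply(seq_len(nrow(fx)), function(i) {
    sc <- scenes[[fx$scene_id[i]]]
    if (is.null(sc)) {
      return(data.frame(n_objects = NA_integer_, n_colors = NA_integer_,
                        on_target = NA, has_keypress = NA))
    }
    as.data.frame(label_epoch(fx[i, ], sc, events, fovea_radius,
                              color_threshold))
  })
  epochs$labels <- do.call(rbind, labs)
  epochs
}

#' Band-pass filter epochs
#'
#' Zero-phase 1--10 Hz band-pass applied per channel and epoch, isolating
#' the slow evoked deflections before single-trial peak fitting.
#'
#' @param epochs an `frp_epochs` object.
#' @param band band edges (Hz).
#' @param order overall filter order.
#' @return the filtered epochs (same shape).
#' @export
bandpass_epochs <- function(epochs, band = c(1, 10), order = 8) {
  stopifnot(inherits(epochs, "frp_epochs"))
  for (e in seq_len(dim(epochs$data)[3])) {
    epochs$data[, , e] <- filter_matrix(epochs$data[, , e], epochs$fs,
                                        band, order)
  }
  epochs
}
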