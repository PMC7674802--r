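#' Canonical EEG frequency bands
#'
#' delta 0.5--4, theta 4--8, alpha1 8--10, alpha2 10--13, beta 13--30 Hz.
#' @return named list of band edges (Hz); membership is half-open
#'   `[lo, hi)`.
#' @export
eeg_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha1 = c(8, 10),
       alpha2 = c(10, 13), beta = c(13, 30))
}

#' Extract the EEG segment spanning one fixation
#'
#' Unlike the fixed 1 s FRP epochs, these segments cover exactly the
#' fixation interval, whatever its duration. The half-open sample rule is
#' `[ceil(onset * fs), ceil(offset * fs))`.
#'
#' @param eeg an `eeg_record`.
#' @param fixation one-row fixation record (`onset`, `offset`, s).
#' @return object of class `"fixation_segment"`: `data` (channels x
#'   samples), `fs`, `channels`, `onset`, `offset`; or `NULL` when the
#'   fixation is not fully inside the recording.
#' @export
extract_segment <- function(eeg, fixation) {
  stopifnot(inherits(eeg, "eeg_record"))
  fs <- eeg$fs
  i0 <- as.integer(ceiling((fixation$onset - eeg$t0) * fs)) + 1L
  i1 <- as.integer(ceiling((fixation$offset - eeg$t0) * fs))
  if (i0 < 1L || i1 > ncol(eeg$data) || i1 < i0) return(NULL)
  structure(list(data = eeg$data[, i0:i1, drop = FALSE], fs = fs,
                 channels = eeg$channels, onset = fixation$onset,
                 offset = fixation$offset),
            class = "fixation_segment")
}

#' Relative bandpower of an EEG segment
#'
#' Per channel: linear detrend, Hann taper, periodogram via FFT evaluated
#' on a zero-padded frequency grid (at least `min_nfft` points) so band
#' power can be integrated over bins finer than the segment's native
#' resolution; power is summed over each band's frequency bins (half-open
#' `[lo, hi)`), the five band powers are normalized to sum to 1 per
#' channel, and channels are averaged. Padding interpolates the spectrum
#' -- it adds no information, but without it a sub-second segment
#' represents the whole delta band by a single coarse bin. Segments still
#' cannot truly resolve the lowest band edges; the remaining bias is
#' identical across conditions and cancels in classification.
#'
#' @param segment a `fixation_segment`, an `eeg_record`, or a bare numeric
#'   matrix (channels x samples) / vector with `fs` supplied.
#' @param bands named list of band edges, see [eeg_bands()].
#' @param channels channel-selection policy: `"eeg"` (average the 16 EEG
#'   channels, default), `"all"`, or a character vector of labels.
#' @param fs sampling rate, required for bare matrices.
#' @param min_nfft minimum FFT length (zero-padding target).
#' @return named numeric vector of band fractions summing to 1.
#' @export
relative_bandpower <- function(segment, bands = eeg_bands(),
                               channels = "eeg", fs = NULL,
                               min_nfft = 1024) {
  if (inherits(segment, c("fixation_segment", "eeg_record"))) {
    fs <- segment$fs
    labels <- segment$channels
    mat <- segment$data
    sel <- if (identical(channels, "eeg")) {
      eeg_channel_idx(labels)
    } else if (identical(channels, "all")) {
      seq_along(labels)
    } else {
      match(channels, labels)
    }
    mat <- mat[sel, , drop = FALSE]
  } else {
    if (is.null(fs)) stop("fs required for a bare matrix", call. = FALSE)
    mat <- if (is.matrix(segment)) segment else matrix(segment, nrow = 1)
  }
  n <- ncol(mat)
  if (all(mat == 0)) {
    stop("relative bandpower undefined for an all-zero segment",
         call. = FALSE)
  }
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))  # Hann
  nfft <- max(n, min_nfft)
  half <- seq_len(floor(nfft / 2))
  freqs <- (half - 1) * fs / nfft

  rel <- sapply(seq_len(nrow(mat)), function(ci) {
    x <- c(detrend_linear(mat[ci, ]) * taper, rep(0, nfft - n))
    p <- Mod(stats::fft(x))^2
    bp <- vapply(bands, function(b) sum(p[half][freqs >= b[1] & freqs < b[2]]),
                 0)
    tot <- sum(bp)
    if (tot == 0) rep(0, length(bands)) else bp / tot
  })
  out <- rowMeans(matrix(rel, nrow = length(bands)))
  out <- out / sum(out)
  names(out) <- names(bands)
  out
}

detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::residuals(stats::lm.fit(cbind(1, t), x))
}

#' Relative bandpower features for a fixation table
#'
#' @param eeg an `eeg_record`.
#' @param fixations fixation table (`onset`, `offset`); rows whose segment
#'   falls outside the recording are dropped.
#' @param keypress optional logical vector marking action fixations.
#' @inheritParams relative_bandpower
#' @return data.frame: fixation, duration_ms, has_keypress, and one
#'   `rel_<band>` column per band; attribute `n_rejected`.
#' @export
bandpower_features <- function(eeg, fixations, keypress = NULL,
                               bands = eeg_bands(), channels = "eeg") {
  rows <- vector("list", nrow(fixations))
  for (i in seq_len(nrow(fixations))) {
    seg <- extract_segment(eeg, fixations[i, ])
    if (is.null(seg)) next
    bp <- relative_bandpower(seg, bands, channels)
    rows[[i]] <- data.frame(
      fixation = i,
      duration_ms = (fixations$offset[i] - fixations$onset[i]) * 1000,
      has_keypress = if (is.null(keypress)) NA else keypress[i],
      as.list(setNames(bp, paste0("rel_", names(bp))))
    )
  }
  kept <- !vapply(rows, is.null, TRUE)
  out <- do.call(rbind, rows[kept])
  attr(out, "n_rejected") <- sum(!kept)
  out
}

#' Classify action vs. exploratory fixations from bandpower features
#'
#' Five relative band powers per fixation segment feed a Fisher
#' discriminant classifier under balanced stratified k-fold
#' cross-validation ([crossvalidate()]); keypress-locked slow potentials
#' raise the relative delta power of action fixations.
#'
#' @param features data.frame from [bandpower_features()] (or any matrix
#'   of per-fixation features).
#' @param labels logical/factor action labels; defaults to the
#'   `has_keypress` column.
#' @param k CV folds.
#' @param eps FDA regularization.
#' @param repeats repetitions of the balanced fold assignment; action
#'   fixations are typically a small minority, so each balanced subsample
#'   keeps only a fraction of the exploratory fixations and repetition
#'   stabilizes the estimate.
#' @return a `cv_result`.
#' @export
classify_action_fixations <- function(features, labels = NULL, k = 5,
                                      eps = 1e-6, repeats = 10) {
  if (is.null(labels)) labels <- features$has_keypress
  if (length(unique(labels)) < 2) {
    stop("action classification needs both classes present", call. = FALSE)
  }
  cols <- grep("^rel_", names(features), value = TRUE)
  x <- as.matrix(features[, cols, drop = FALSE])
  crossvalidate(x, factor(labels), k = k, eps = eps, repeats = repeats)
}

#' Fixation-duration distributions by action class
#'
#' Compares the duration distributions of keypress (action) and
#' non-keypress (exploratory) fixations: normalized histograms on common
#' breaks, a two-sample Wilcoxon rank-sum location test, and the
#' histogram overlap coefficient (action and exploratory durations overlap
#' considerably even when their medians differ).
#'
#' @param durations_ms fixation durations (ms).
#' @param keypress logical action labels.
#' @param binwidth_ms histogram bin width (ms).
#' @return list of class `"duration_stats"`: `median_action`,
#'   `median_nonaction`, `p_value`, `overlap`, `breaks`, `density_action`,
#'   `density_nonaction` (each density sums to 1).
#' @export
duration_stats <- function(durations_ms, keypress, binwidth_ms = 50) {
  stopifnot(length(durations_ms) == length(keypress))
  a <- durations_ms[keypress]
  b <- durations_ms[!keypress]
  if (!length(a) || !length(b)) {
    stop("duration comparison needs both classes present", call. = FALSE)
  }
  breaks <- seq(0, max(durations_ms) + binwidth_ms, by = binwidth_ms)
  ha <- graphics::hist(a, breaks = breaks, plot = FALSE)$counts
  hb <- graphics::hist(b, breaks = breaks, plot = FALSE)$counts
  da <- ha / sum(ha); db <- hb / sum(hb)
  wt <- stats::wilcox.test(a, b, exact = FALSE)
  structure(list(median_action = stats::median(a),
                 median_nonaction = stats::median(b),
                 p_value = wt$p.value,
                 overlap = sum(pmin(da, db)),
                 breaks = breaks, density_action = da,
                 density_nonaction = db),
            class = "duration_stats")
}

#' @export
print.duration_stats <- function(x, ...) {
  cat(sprintf(paste0("<duration_stats> median action %.0f ms vs ",
                     "exploratory %.0f ms (p = %.3g, overlap %.2f)\n"),
              x$median_action, x$median_nonaction, x$p_value, x$overlap))
  invisible(x)
}
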