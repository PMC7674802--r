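#' Standard montage labels
#'
#' 16 EEG channels (10-20 positions) plus 4 EOG channels.
#' @return character vector of 20 labels; EEG first, EOG last.
#' @export
default_montage <- function() {
  c("Fz", "Cz", "Pz", "Oz", "F3", "C3", "P3", "F4", "C4", "P4",
    "PO8", "PO7", "F7", "F8", "T7", "T8",
    "HEOGL", "HEOGR", "VEOGU", "VEOGD")
}

eeg_channel_idx <- function(channels) which(!grepl("EOG", channels))
eog_channel_idx <- function(channels) which(grepl("EOG", channels))

#' Neural simulation parameters
#'
#' Controls the evoked and background activity of the synthetic EEG. Each
#' fixation contributes a P100-like occipital deflection at
#' `p100_latency_ms` after fixation onset whose amplitude is
#' `base + gain_per_object * n_objects + gain_per_color * n_colors +
#' gain_target * [on target]` microvolts plus Gaussian trial-to-trial
#' variability. Keypress fixations additionally contribute a slow
#' centro-parietal oscillatory transient (a Gaussian-windowed
#' `keypress_freq_hz` carrier, ~3 Hz by default, i.e. upper-delta-band
#' energy), emulating the biphasic movement/feedback-locked potential
#' complexes seen time-locked to key presses. Background activity is
#' 1/f-shaped noise plus
#' white sensor noise; EOG channels carry gaze-locked potentials and
#' optional blinks that leak into frontal EEG channels.
#'
#' @param fs EEG sampling rate (Hz).
#' @param p100_latency_ms P100 latency after fixation onset (90--100 ms).
#' @param p100_sigma_ms Gaussian width of the P100 deflection.
#' @param p100_base_amp,gain_per_object,gain_per_color,gain_target µV.
#' @param amp_jitter_sd trial-to-trial amplitude SD (µV).
#' @param keypress_delta_amp amplitude of the keypress-locked slow wave (µV).
#' @param keypress_sigma_ms Gaussian envelope width of the slow wave.
#' @param keypress_freq_hz carrier frequency of the slow wave (delta band).
#' @param noise_pink_uv RMS of the 1/f background per channel (µV).
#' @param noise_white_uv RMS of white sensor noise per channel (µV).
#' @param blink_rate blink events per second on the vertical EOG.
#' @param blink_amp blink amplitude on VEOG (µV).
#' @param eog_leak fraction of the EOG signal leaking into frontal EEG.
#' @return list of class `"neural_params"`.
#' @export
neural_params <- function(fs = 256,
                          p100_latency_ms = 95,
                          p100_sigma_ms = 15,
                          p100_base_amp = 5,
                          gain_per_object = 1.5,
                          gain_per_color = 1.0,
                          gain_target = 1.0,
                          amp_jitter_sd = 1.0,
                          keypress_delta_amp = 20,
                          keypress_sigma_ms = 150,
                          keypress_freq_hz = 3,
                          noise_pink_uv = 10,
                          noise_white_uv = 2,
                          blink_rate = 0.1,
                          blink_amp = 80,
                          eog_leak = 0.1) {
  stopifnot(fs > 0, p100_latency_ms >= 90, p100_latency_ms <= 100,
            gain_per_object >= 0, gain_per_color >= 0, gain_target >= 0,
            noise_pink_uv >= 0, noise_white_uv >= 0)
  structure(as.list(environment()), class = "neural_params")
}

# per-channel weight of the P100 source (occipital maximum at Oz)
p100_topography <- function(channels) {
  w <- setNames(rep(0.1, length(channels)), channels)
  occ <- c(Oz = 1, PO7 = 0.7, PO8 = 0.7, Pz = 0.5, P3 = 0.4, P4 = 0.4)
  w[names(occ)[names(occ) %in% channels]] <- occ[names(occ) %in% channels]
  w[grepl("EOG", channels)] <- 0
  w
}

# centro-parietal topography for the keypress-locked slow wave
keypress_topography <- function(channels) {
  w <- setNames(rep(0.3, length(channels)), channels)
  ctr <- c(Cz = 1, Pz = 0.8, C3 = 0.7, C4 = 0.7, Fz = 0.6)
  w[names(ctr)[names(ctr) %in% channels]] <- ctr[names(ctr) %in% channels]
  w[grepl("EOG", channels)] <- 0
  w
}

# 1/f-shaped noise, unit RMS
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))          # avoid div-by-zero at DC
  f <- pmin(f, n - f + 1)            # mirror for negative frequencies
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

gauss_bump <- function(t, center, sigma) exp(-(t - center)^2 / (2 * sigma^2))

#' Simulate a continuous multichannel EEG record
#'
#' @param truth ground-truth fixation table as produced by
#'   [simulate_gaze()] (columns onset, n_objects, n_colors, on_target,
#'   keypress, keypress_time), on the session clock.
#' @param params a [neural_params()] list.
#' @param duration record length in seconds.
#' @param channels montage labels (EEG + EOG).
#' @param gaze optional dominant-eye gaze table used to drive the EOG
#'   channels (gaze-position potentials).
#' @return object of class `"eeg_record"`: list with `fs`, `channels`,
#'   `data` (channels x samples matrix, µV) and `t0`.
#' @export
simulate_eeg <- function(truth, params = neural_params(), duration,
                         channels = default_montage(), gaze = NULL) {
  stopifnot(inherits(params, "neural_params"), duration > 0)
  fs <- params$fs
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1L) / fs
  nch <- length(channels)
  data <- matrix(0, nch, n, dimnames = list(channels, NULL))

  for (ci in seq_len(nch)) {
    x <- 0
    if (params$noise_pink_uv > 0) x <- x + params$noise_pink_uv * pink_noise(n)
    if (params$noise_white_uv > 0) x <- x + stats::rnorm(n, 0, params$noise_white_uv)
    data[ci, ] <- x
  }

  topo_p100 <- p100_topography(channels)
  topo_kp <- keypress_topography(channels)
  lat <- params$p100_latency_ms / 1000
  sig <- params$p100_sigma_ms / 1000
  kp_sig <- params$keypress_sigma_ms / 1000

  if (!is.null(truth) && nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      amp <- params$p100_base_amp +
        params$gain_per_object * truth$n_objects[i] +
        params$gain_per_color * truth$n_colors[i] +
        params$gain_target * as.numeric(truth$on_target[i]) +
        stats::rnorm(1, 0, params$amp_jitter_sd)
      ctr <- truth$onset[i] + lat
      idx <- which(t >= ctr - 4 * sig & t <= ctr + 4 * sig)
      if (length(idx)) {
        bump <- amp * gauss_bump(t[idx], ctr, sig)
        data[, idx] <- data[, idx] + outer(topo_p100, bump)
      }
      if (isTRUE(truth$keypress[i]) && is.finite(truth$keypress_time[i])) {
        kc <- truth$keypress_time[i]
        idx <- which(t >= kc - 4 * kp_sig & t <= kc + 4 * kp_sig)
        if (length(idx)) {
          # biphasic slow complex: Gaussian-windowed delta-band carrier
          bump <- params$keypress_delta_amp * gauss_bump(t[idx], kc, kp_sig) *
            cos(2 * pi * params$keypress_freq_hz * (t[idx] - kc))
          data[, idx] <- data[, idx] + outer(topo_kp, bump)
        }
      }
    }
  }

  # EOG: gaze-position potentials (saccade-locked steps) + blinks
  eog <- eog_channel_idx(channels)
  if (length(eog) && !is.null(gaze) && nrow(gaze) > 0) {
    g <- select_eye(gaze, "R")
    hx <- stats::approx(g$t_sec, g$x_px, xout = t, method = "constant",
                        rule = 2)$y
    vy <- stats::approx(g$t_sec, g$y_px, xout = t, method = "constant",
                        rule = 2)$y
    heog <- 0.05 * (hx - mean(hx))
    veog <- 0.05 * (vy - mean(vy))
    lab <- channels[eog]
    add <- rbind(heog, -heog, veog, -veog)[seq_along(eog), , drop = FALSE]
    data[eog, ] <- data[eog, ] + add
  }
  if (length(eog) && params$blink_rate > 0) {
    n_blinks <- stats::rpois(1, params$blink_rate * duration)
    if (n_blinks > 0) {
      centers <- sort(stats::runif(n_blinks, 0, duration))
      blink <- rep(0, n)
      for (bc in centers) {
        idx <- which(t >= bc - 0.2 & t <= bc + 0.2)
        blink[idx] <- blink[idx] + params$blink_amp * gauss_bump(t[idx], bc, 0.05)
      }
      vup <- which(channels == "VEOGU"); vdn <- which(channels == "VEOGD")
      if (length(vup)) data[vup, ] <- data[vup, ] + blink
      if (length(vdn)) data[vdn, ] <- data[vdn, ] - blink
      if (params$eog_leak > 0) {
        frontal <- which(channels %in% c("Fz", "F3", "F4", "F7", "F8"))
        data[frontal, ] <- data[frontal, ] +
          params$eog_leak * matrix(blink, length(frontal), n, byrow = TRUE)
      }
    }
  }

  structure(list(fs = fs, channels = channels, data = data, t0 = 0,
                 units = "uV"), class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}
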