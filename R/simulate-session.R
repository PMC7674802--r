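#' Simulate a full recording session
#'
#' Chains the stimulus, gaze and EEG generators into a complete
#' co-registered session: a balanced scene schedule, a continuous gaze
#' stream, a 16+4-channel EEG record, an event log (scene onsets, search
#' reveals, keypresses, feedback), per-fixation ground truth, and an
#' injected eye-tracker clock error (static offset + linear drift).
#'
#' Session timeline per scene: `scene_on`, 1 s of target-panel preview,
#' `search_reveal`, the scene's gaze stream, then a 0.5 s gap.
#'
#' @param n_per_condition scenes per condition (study value: 23).
#' @param missing_rate fraction of missing-target scenes (study value 0.08).
#' @param behavior a [behavior_params()] list.
#' @param neural a [neural_params()] list.
#' @param clock_offset,clock_drift injected eye-tracker clock error: ET
#'   timestamps are `offset + drift * t_session`.
#' @param n_fix_per_scene optional fixed fixation count per scene.
#' @return object of class `"frp_session"`: list with `schedule`, `gaze`
#'   (ET clock), `eeg`, `events` (session clock), `truth` (session clock,
#'   plus scene ids) and `clock` (the injected pair and ET-side keypress
#'   times for resynchronization).
#' @export
simulate_session <- function(n_per_condition = 2, missing_rate = 0.08,
                             behavior = behavior_params(),
                             neural = neural_params(),
                             clock_offset = 0.5, clock_drift = 1.001,
                             n_fix_per_scene = NULL) {
  schedule <- generate_schedule(n_per_condition, missing_rate)
  t <- 0
  gaze_parts <- list(); truth_parts <- list(); events <- list()
  for (i in seq_along(schedule$scenes)) {
    scene <- schedule$scenes[[i]]
    events[[length(events) + 1L]] <- list(t = t, type = "scene_on",
                                          scene_id = scene$scene_id)
    t <- t + 1
    events[[length(events) + 1L]] <- list(t = t, type = "search_reveal",
                                          scene_id = scene$scene_id)
    sim <- simulate_gaze(scene, behavior, t0 = t, n_fix = n_fix_per_scene)
    sim$truth$scene_id <- scene$scene_id
    gaze_parts[[i]] <- sim$gaze
    truth_parts[[i]] <- sim$truth
    kp <- sim$truth$keypress_time[sim$truth$keypress]
    for (ktime in kp) {
      events[[length(events) + 1L]] <- list(t = ktime, type = "keypress",
                                            scene_id = scene$scene_id)
      events[[length(events) + 1L]] <- list(t = ktime + 0.2, type = "feedback",
                                            scene_id = scene$scene_id)
    }
    t <- sim$t_end + 0.5
  }
  gaze <- do.call(rbind, gaze_parts)
  truth <- do.call(rbind, truth_parts)
  rownames(gaze) <- rownames(truth) <- NULL
  ord <- order(vapply(events, `[[`, 0, "t"))
  events <- events[ord]

  eeg <- simulate_eeg(truth, neural, duration = t + 1, gaze = gaze)

  session <- structure(list(
    schedule = schedule, gaze = gaze, eeg = eeg, events = events,
    truth = truth,
    clock = list(offset = 0, drift = 1, et_keypress = numeric(0))
  ), class = "frp_session")
  inject_clock_error(session, clock_offset, clock_drift,
                     fs_et = behavior$fs_et)
}

#' Inject eye-tracker clock error into a session
#'
#' Transforms all eye-tracker-side timestamps by the affine map
#' `t_et = offset + drift * t_session` and records the injected pair in the
#' session's `clock` field. ET-side keypress timestamps (used later as
#' matched events for resynchronization) are quantized to the ET frame
#' grid, emulating the tracker's discrete logging.
#'
#' @param session an `frp_session` whose gaze is on the session clock.
#' @param offset static offset (s).
#' @param drift clock-rate ratio, near 1 (|drift - 1| <= 0.01).
#' @param fs_et ET frame rate used for timestamp quantization.
#' @return the session with transformed gaze timestamps and updated `clock`.
#' @export
inject_clock_error <- function(session, offset, drift, fs_et = 60) {
  stopifnot(inherits(session, "frp_session"), abs(drift - 1) <= 0.01)
  # compose with any previously injected error (identity by default)
  old <- session$clock
  session$gaze$t_sec <- offset + drift * session$gaze$t_sec
  kp_session <- session$truth$keypress_time[session$truth$keypress]
  et_kp <- offset + drift * (old$offset + old$drift * kp_session)
  session$clock <- list(
    offset = offset + drift * old$offset,
    drift = drift * old$drift,
    et_keypress = round(et_kp * fs_et) / fs_et
  )
  session
}

#' @export
print.frp_session <- function(x, ...) {
  cat(sprintf(paste0("<frp_session> %d scenes, %d fixations ",
                     "(%d with keypress), %.1f s EEG @ %g Hz\n"),
              length(x$schedule$scenes), nrow(x$truth),
              sum(x$truth$keypress), ncol(x$eeg$data) / x$eeg$fs, x$eeg$fs))
  cat(sprintf("  injected clock error: offset %.4g s, drift %.6g\n",
              x$clock$offset, x$clock$drift))
  invisible(x)
}
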