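#' Estimate the EEG--eye-tracker clock relation
#'
#' The two recording devices run on different computers whose clocks show a
#' static offset plus a linear drift. Using events logged on both clocks
#' (keypresses here), the affine relation
#' \deqn{t_{et} = \mathrm{offset} + \mathrm{drift} \cdot t_{eeg}}
#' is fitted by least squares. [apply_sync()] inverts the map to bring
#' eye-tracker timestamps onto the session (EEG) clock; all downstream
#' stages consume resynchronized time only.
#'
#' @param eeg_times event times on the session/EEG clock (s).
#' @param et_times the same events on the eye-tracker clock (s); matched
#'   pairwise with `eeg_times`.
#' @param drift_bounds admissible drift range; a fit outside it errors.
#' @param residual_warn RMS residual (s) above which a warning is issued.
#' @return object of class `"sync_model"`: `offset` (s), `drift`,
#'   `n_pairs`, `residual_rms` (s).
#' @export
estimate_sync <- function(eeg_times, et_times,
                          drift_bounds = c(0.99, 1.01),
                          residual_warn = 0.05) {
  stopifnot(length(eeg_times) == length(et_times))
  if (length(eeg_times) < 2) {
    stop("resynchronization needs at least 2 matched event pairs",
         call. = FALSE)
  }
  fit <- stats::lm(et_times ~ eeg_times)
  offset <- unname(stats::coef(fit)[1])
  drift <- unname(stats::coef(fit)[2])
  if (drift < drift_bounds[1] || drift > drift_bounds[2]) {
    stop(sprintf("fitted clock drift %.6f outside admissible bounds [%g, %g]",
                 drift, drift_bounds[1], drift_bounds[2]), call. = FALSE)
  }
  rms <- sqrt(mean(stats::residuals(fit)^2))
  if (rms > residual_warn) {
    warning(sprintf("sync residual RMS %.4f s exceeds %.4f s",
                    rms, residual_warn), call. = FALSE)
  }
  structure(list(offset = offset, drift = drift,
                 n_pairs = length(eeg_times), residual_rms = rms),
            class = "sync_model")
}

#' @export
print.sync_model <- function(x, ...) {
  cat(sprintf("<sync_model> offset %.4f s, drift %.6f (%d pairs, RMS %.2g s)\n",
              x$offset, x$drift, x$n_pairs, x$residual_rms))
  invisible(x)
}

#' Map eye-tracker timestamps onto the session clock
#'
#' @param gaze gaze table with column `t_sec` on the ET clock (or a bare
#'   numeric vector of timestamps).
#' @param model a [estimate_sync()] fit.
#' @return the gaze table (or vector) with timestamps on the session clock.
#' @export
apply_sync <- function(gaze, model) {
  stopifnot(inherits(model, "sync_model"))
  if (is.numeric(gaze)) return((gaze - model$offset) / model$drift)
  gaze$t_sec <- (gaze$t_sec - model$offset) / model$drift
  gaze
}

#' @export
predict.sync_model <- function(object, eeg_times, ...) {
  object$offset + object$drift * eeg_times
}
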