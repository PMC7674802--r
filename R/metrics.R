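#' Time-independent gaze-difficulty metrics for one scene
#'
#' Three within-scene ratios summarizing the gaze pattern independently of
#' scene-completion time:
#'
#' * **M1** — fraction of fixations longer than `long_threshold` ms
#'   (long fixations, default 250 ms).
#' * **M2** — fraction of inter-fixation movements landing outside the
#'   foveal region (radius `fovea_radius` px) of the previous fixation
#'   (distant saccades).
#' * **M3** — fraction of fixations landing within the foveal region of
#'   any earlier fixation (revisits; the first fixation can never be one,
#'   and a fixation counts once however many prior regions it overlaps).
#'
#' @param fixations fixation table for one scene (columns `x`, `y`,
#'   `duration` in seconds); at least 2 fixations.
#' @param fovea_radius foveal radius in px.
#' @param long_threshold long-fixation threshold in ms.
#' @return named numeric vector `c(m1, m2, m3)`, each in [0, 1].
#' @export
compute_gaze_metrics <- function(fixations, fovea_radius = 80,
                                 long_threshold = 250) {
  n <- nrow(fixations)
  if (is.null(n) || n < 2) {
    stop("gaze metrics are undefined for scenes with fewer than 2 fixations",
         call. = FALSE)
  }
  m1 <- mean(fixations$duration * 1000 > long_threshold)

  dx <- diff(fixations$x); dy <- diff(fixations$y)
  m2 <- mean(sqrt(dx^2 + dy^2) > fovea_radius)

  revisit <- logical(n)
  for (i in 2:n) {
    d <- sqrt((fixations$x[seq_len(i - 1)] - fixations$x[i])^2 +
              (fixations$y[seq_len(i - 1)] - fixations$y[i])^2)
    revisit[i] <- any(d <= fovea_radius)
  }
  m3 <- mean(revisit)

  c(m1 = m1, m2 = m2, m3 = m3)
}

#' Per-scene gaze metrics for a whole session
#'
#' @param fixations fixation table with a `scene_id` column.
#' @param conditions optional data.frame (scene_id, condition labels) to
#'   join onto the result.
#' @param min_fixations scenes with fewer fixations are skipped.
#' @inheritParams compute_gaze_metrics
#' @return data.frame: scene_id, m1, m2, m3 (+ condition columns).
#' @export
session_gaze_metrics <- function(fixations, conditions = NULL,
                                 fovea_radius = 80, long_threshold = 250,
                                 min_fixations = 2) {
  ids <- unique(fixations$scene_id)
  rows <- lapply(ids, function(id) {
    fx <- fixations[fixations$scene_id == id, , drop = FALSE]
    if (nrow(fx) < min_fixations) return(NULL)
    m <- compute_gaze_metrics(fx, fovea_radius, long_threshold)
    data.frame(scene_id = id, m1 = m["m1"], m2 = m["m2"], m3 = m["m3"],
               row.names = NULL)
  })
  res <- do.call(rbind, rows)
  if (!is.null(conditions) && !is.null(res)) {
    res <- merge(res, conditions, by = "scene_id", sort = FALSE)
  }
  res
}
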