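#' Gaze-behavior parameters
#'
#' Defaults emulate the behavioral trends of the search task: scenes with
#' more objects draw more fixations, and higher target/distractor color
#' similarity drives more revisits of the target panel. Fixation durations
#' are `min + Gamma(shape, scale)` milliseconds, supported above 100 ms with
#' mode near 250 ms (the canonical average fixation duration).
#'
#' @param fs_et eye-tracker sampling rate per eye (Hz).
#' @param fix_dur_min_ms,fix_dur_shape,fix_dur_scale_ms fixation-duration
#'   distribution: `min + Gamma(shape, scale)` ms.
#' @param n_fix_mean mean exploratory fixations per scene by object-count
#'   level. The defaults put slightly more fixations per shape on crowded
#'   scenes (inefficient search revisits more as displays grow), which is
#'   what makes object count recoverable from time-independent gaze
#'   ratios.
#' @param revisit_prob probability that a fixation lands on the target panel,
#'   by color-similarity level.
#' @param saccade_min_px minimum center distance between consecutive
#'   fixations (px); must exceed the 80 px fixation-break jump plus twice
#'   the jitter bound so detection can separate them.
#' @param landing_sd_px saccadic landing error: fixations land a truncated
#'   Gaussian offset (SD `landing_sd_px`, capped at 40 px) away from the
#'   aimed shape center, so shapes spaced near the foveal diameter can
#'   jointly enter the foveal region.
#' @param jitter_sd_px within-fixation positional jitter SD (px), truncated
#'   at `jitter_max_px` so every sample stays well inside the 80 px-diameter
#'   dispersion circle.
#' @param jitter_max_px truncation bound for the jitter (px).
#' @param keypress_prob probability of a space press during a fixation on a
#'   target shape in the search panel.
#' @param keypress_extra_ms extra duration added to keypress fixations.
#'   The default is 0 so that, with the keypress-locked EEG component
#'   switched off, action and exploratory fixations are statistically
#'   identical (a clean null for classifier calibration); set it positive
#'   (e.g. 150) to emulate the longer action fixations seen in real data.
#' @return list of class `"behavior_params"`.
#' @export
behavior_params <- function(fs_et = 60,
                            fix_dur_min_ms = 100,
                            fix_dur_shape = 3,
                            fix_dur_scale_ms = 75,
                            n_fix_mean = c(few = 16, many = 40),
                            revisit_prob = c(high = 0.35, medium = 0.25,
                                             low = 0.12),
                            saccade_min_px = 130,
                            landing_sd_px = 20,
                            jitter_sd_px = 8,
                            jitter_max_px = 18,
                            keypress_prob = 0.8,
                            keypress_extra_ms = 0) {
  stopifnot(fs_et > 0, all(n_fix_mean > 0), all(revisit_prob >= 0),
            jitter_max_px < 40, saccade_min_px > 80 + 2 * jitter_max_px)
  structure(as.list(environment()), class = "behavior_params")
}

# visits each target needs before being selected: geometric retries, the
# final visit carries the space press; missing targets are selected on the
# target panel (the panel shape absent from the search scene)
selection_queue <- function(scene, params) {
  rows <- list()
  tgt <- scene$search_shapes[scene$search_shapes$is_target, , drop = FALSE]
  add <- function(x, y, panel) {
    n_visits <- 1L + min(stats::rgeom(1, params$keypress_prob), 2L)
    for (v in seq_len(n_visits)) {
      land <- truncated_jitter(1, params$landing_sd_px, 40)[1, ]
      rows[[length(rows) + 1L]] <<- data.frame(
        x = x + land[1], y = y + land[2], panel = panel,
        press = (v == n_visits))
    }
  }
  for (i in seq_len(nrow(tgt))) add(tgt$x[i], tgt$y[i], "search")
  if (isTRUE(scene$missing_target)) {
    miss <- nrow(scene$target_shapes)   # the shape withheld from the search
    add(scene$target_shapes$x[miss], scene$target_shapes$y[miss], "target")
  }
  if (!length(rows)) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      panel = character(0), press = logical(0)))
  }
  do.call(rbind, rows)
}

# truncated gaussian jitter, bounded in euclidean norm
truncated_jitter <- function(n, sd, max_r) {
  dx <- stats::rnorm(n, 0, sd); dy <- stats::rnorm(n, 0, sd)
  r <- sqrt(dx^2 + dy^2)
  bad <- r > max_r
  if (any(bad)) {
    scl <- max_r / r[bad]
    dx[bad] <- dx[bad] * scl; dy[bad] <- dy[bad] * scl
  }
  cbind(dx, dy)
}

#' Simulate the gaze stream for one scene
#'
#' Generates a piecewise-constant fixation sequence (instantaneous
#' saccades) sampled at the eye-tracker rate, with truncated Gaussian
#' within-fixation jitter, plus the ground-truth fixation table. The
#' sequence interleaves exploratory fixations -- alternating between the
#' search panel and (with a similarity-dependent revisit probability) the
#' target panel -- with selection fixations: the task completes a scene by
#' selecting every target, so each search-panel target receives a fixation
#' during which the space key is pressed (with probability
#' `keypress_prob` per visit; unselected targets are revisited). In
#' missing-target scenes the absent target is selected on the target
#' panel.
#'
#' @param scene an `frp_scene`.
#' @param params a [behavior_params()] list.
#' @param t0 session time (s) at which the scene's gaze stream starts.
#' @param n_fix optional fixed number of exploratory fixations (otherwise
#'   Poisson with the condition's mean, minimum 4); selection fixations
#'   are added on top.
#' @return list with `gaze` (data.frame: t_sec, eye, x_px, y_px, valid; the
#'   dominant eye is `"R"`), `truth` (data.frame: onset, offset, x, y,
#'   duration, n_frames, panel, n_objects, n_colors, on_target, keypress,
#'   keypress_time), and `t_end`.
#' @export
simulate_gaze <- function(scene, params = behavior_params(), t0 = 0,
                          n_fix = NULL) {
  stopifnot(inherits(scene, "frp_scene"), inherits(params, "behavior_params"))
  fs <- params$fs_et
  if (is.null(n_fix)) {
    n_fix <- max(4L, stats::rpois(1, params$n_fix_mean[[scene$object_count]]))
  }
  p_revisit <- params$revisit_prob[[scene$color_similarity]]

  centers <- matrix(NA_real_, n_fix, 2)
  panel <- character(n_fix)
  prev <- c(-1e6, -1e6)
  n_search <- nrow(scene$search_shapes)
  for (i in seq_len(n_fix)) {
    for (attempt in 1:200) {
      on_target_panel <- stats::runif(1) < p_revisit
      if (on_target_panel) {
        j <- sample.int(nrow(scene$target_shapes), 1)
        ctr <- c(scene$target_shapes$x[j], scene$target_shapes$y[j])
      } else {
        j <- sample.int(n_search, 1)
        ctr <- c(scene$search_shapes$x[j], scene$search_shapes$y[j])
      }
      ctr <- ctr + truncated_jitter(1, params$landing_sd_px, 40)[1, ]
      if (sqrt(sum((ctr - prev)^2)) >= params$saccade_min_px) break
    }
    centers[i, ] <- ctr
    panel[i] <- if (on_target_panel) "target" else "search"
    prev <- ctr
  }
  keypress <- logical(n_fix)

  # selection fixations: the scene completes by selecting every target, so
  # each target contributes visits ending in a keypress, interleaved at
  # random positions among the exploratory fixations
  sel <- selection_queue(scene, params)
  if (nrow(sel) > 0) {
    total <- n_fix + nrow(sel)
    sel_pos <- sort(sample.int(total, nrow(sel)))
    all_centers <- matrix(NA_real_, total, 2)
    all_panel <- character(total); all_press <- logical(total)
    all_centers[sel_pos, ] <- cbind(sel$x, sel$y)
    all_panel[sel_pos] <- sel$panel
    all_press[sel_pos] <- sel$press
    expl <- setdiff(seq_len(total), sel_pos)
    all_centers[expl, ] <- centers
    all_panel[expl] <- panel
    # drop exploratory fixations that break the saccade spacing around an
    # inserted selection; between two close selections drop the earlier
    keep <- rep(TRUE, total)
    for (i in 2:total) {
      prev_i <- which(keep[seq_len(i - 1L)])
      if (!length(prev_i)) next
      prev_i <- max(prev_i)
      if (sqrt(sum((all_centers[i, ] - all_centers[prev_i, ])^2)) <
          params$saccade_min_px) {
        if (!all_press[i] && i %in% expl) keep[i] <- FALSE
        else keep[prev_i] <- FALSE
      }
    }
    centers <- all_centers[keep, , drop = FALSE]
    panel <- all_panel[keep]
    keypress <- all_press[keep]
  }
  n_fix <- nrow(centers)

  dur_ms <- params$fix_dur_min_ms +
    stats::rgamma(n_fix, shape = params$fix_dur_shape,
                  scale = params$fix_dur_scale_ms)
  dur_ms <- dur_ms + ifelse(keypress, params$keypress_extra_ms, 0)
  n_frames <- pmax(6L, as.integer(round(dur_ms / 1000 * fs)))

  frame <- 0L
  rows <- vector("list", n_fix)
  truth <- vector("list", n_fix)
  for (i in seq_len(n_fix)) {
    idx <- frame + seq_len(n_frames[i]) - 1L
    t <- t0 + idx / fs
    jit <- truncated_jitter(n_frames[i], params$jitter_sd_px,
                            params$jitter_max_px)
    x <- centers[i, 1] + jit[, 1]
    y <- centers[i, 2] + jit[, 2]
    rows[[i]] <- data.frame(t_sec = t, x_px = x, y_px = y)
    onset <- t[1]; offset <- t[n_frames[i]] + 1 / fs
    kp_time <- if (keypress[i]) onset + stats::runif(1, 0.3, 0.8) *
        (offset - onset) else NA_real_
    content <- foveal_content(scene, c(mean(x), mean(y)))
    truth[[i]] <- data.frame(
      onset = onset, offset = offset, x = mean(x), y = mean(y),
      duration = offset - onset, n_frames = n_frames[i], panel = panel[i],
      n_objects = content$n_objects, n_colors = content$n_colors,
      on_target = content$on_target, keypress = keypress[i],
      keypress_time = kp_time, stringsAsFactors = FALSE
    )
    frame <- frame + n_frames[i]
  }
  dom <- do.call(rbind, rows)
  # dominant eye R; mirrored L stream with 1 px sensor jitter
  gaze <- rbind(
    data.frame(t_sec = dom$t_sec, eye = "R", x_px = dom$x_px,
               y_px = dom$y_px, valid = TRUE, stringsAsFactors = FALSE),
    data.frame(t_sec = dom$t_sec, eye = "L",
               x_px = dom$x_px + stats::rnorm(nrow(dom), 0, 1),
               y_px = dom$y_px + stats::rnorm(nrow(dom), 0, 1),
               valid = TRUE, stringsAsFactors = FALSE)
  )
  gaze <- gaze[order(gaze$t_sec, gaze$eye), ]
  rownames(gaze) <- NULL
  list(gaze = gaze, truth = do.call(rbind, truth), t_end = t0 + frame / fs)
}
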