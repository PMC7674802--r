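#' Pipeline configuration
#'
#' Collects every stage parameter with the study's values as defaults:
#' 0.1 Hz highpass, 8th-order 45--55 Hz Butterworth notch, 80 px-diameter /
#' 6-frame / 100 ms dispersion fixation detection with an 80 px break jump,
#' 1 s epochs from 100 ms pre-onset, 1--10 Hz epoch bandpass, Oz analysis
#' channel with a 50--150 ms peak-search window, 80 px foveal radius,
#' 250 ms long-fixation threshold, color-difference threshold 200, the five
#' canonical bands, and five-fold balanced cross-validation.
#'
#' @param ... overrides for any default field.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    highpass_hz = 0.1,
    notch_band = c(45, 55),
    notch_order = 8,
    artifact_removal = TRUE,
    eog_cor_threshold = 0.7,
    dispersion_diameter = 80,
    min_frames = 6,
    min_duration = 0.100,
    break_jump = 80,
    dominant_eye = "R",
    epoch_window = c(-0.1, 0.9),
    epoch_band = c(1, 10),
    analysis_channel = "Oz",
    search_window = c(0.050, 0.150),
    n_regressors = 3,
    lat_jitter_ms = 20,
    width_jitter = 0.3,
    fovea_radius = 80,
    long_threshold_ms = 250,
    color_threshold = 200,
    bands = eeg_bands(),
    cv_folds = 5,
    cv_repeats = 10,
    fda_eps = 1e-6,
    min_template_epochs = 20,
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  if (cfg$cv_folds < 1) stop("cv_folds must be >= 1", call. = FALSE)
  if (cfg$highpass_hz <= 0) stop("highpass_hz must be > 0", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline on a recording bundle
#'
#' Stages: EEG filtering (highpass + notch), optional ICA artifact
#' removal, EEG--eye-tracker resynchronization from matched keypress
#' events, dispersion fixation detection, per-scene gaze-difficulty
#' metrics with FDA cross-validation, fixation-locked P100 amplitude
#' estimation (MLRd) with group comparisons, and fixation-bound relative
#' bandpower classification of action vs. exploratory fixations.
#' Deterministic given `config$seed`.
#'
#' @param bundle a `recording_bundle` (or `frp_session`).
#' @param config a [pipeline_config()].
#' @return list of class `"frp_report"` with elements `sync`, `fixations`,
#'   `metrics`, `gaze_cv`, `peaks`, `comparisons`, `bandpower_cv`,
#'   `durations`, `log`.
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  if (inherits(bundle, "frp_session")) bundle <- as_bundle(bundle)
  stopifnot(inherits(bundle, "recording_bundle"),
            inherits(config, "pipeline_config"))
  set.seed(config$seed)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  # -- preprocessing ---------------------------------------------------
  eeg <- tryCatch({
    e <- highpass_filter(bundle$eeg, config$highpass_hz)
    notch_filter(e, config$notch_band, config$notch_order)
  }, error = function(e) stop("stage filtering: ", conditionMessage(e),
                              call. = FALSE))
  if (isTRUE(config$artifact_removal)) {
    ar <- tryCatch(remove_artifacts(eeg, config$eog_cor_threshold),
                   error = function(e) stop("stage artifact-removal: ",
                                            conditionMessage(e),
                                            call. = FALSE))
    eeg <- ar$eeg
    note("artifact removal: %d/%d components rejected",
         sum(ar$report$rejected), nrow(ar$report))
  }

  sync <- NULL
  gaze <- bundle$gaze
  et_kp <- bundle$truth$clock$et_keypress
  eeg_kp <- event_times(bundle$events, "keypress")
  if (!is.null(et_kp) && length(et_kp) >= 2 &&
      length(et_kp) == length(eeg_kp)) {
    sync <- estimate_sync(eeg_kp, et_kp)
    gaze <- apply_sync(gaze, sync)
    note("resync: offset %.4f s, drift %.6f from %d pairs",
         sync$offset, sync$drift, sync$n_pairs)
  } else {
    note("resync skipped: no matched event pairs; clocks assumed aligned")
  }

  fixations <- detect_fixations(gaze, config$dispersion_diameter,
                                config$min_frames, config$break_jump,
                                config$min_duration, config$dominant_eye)
  note("fixation detection: %d fixations", nrow(fixations))
  fixations$scene_id <- assign_scene(fixations$onset, bundle$events)

  # -- gaze difficulty -------------------------------------------------
  conditions <- bundle$truth$conditions
  metrics <- session_gaze_metrics(fixations, conditions,
                                  config$fovea_radius,
                                  config$long_threshold_ms)
  gaze_cv <- list()
  if (!is.null(metrics) && !is.null(conditions)) {
    feats <- as.matrix(metrics[, c("m1", "m2", "m3")])
    for (lab in c("object_count", "color_similarity")) {
      y <- factor(metrics[[lab]])
      if (nlevels(y) >= 2 && all(table(y) >= config$cv_folds)) {
        gaze_cv[[lab]] <- crossvalidate(feats, y, config$cv_folds,
                                        config$fda_eps)
      }
    }
    y6 <- factor(paste(metrics$object_count, metrics$color_similarity))
    if (nlevels(y6) >= 2 && all(table(y6) >= config$cv_folds)) {
      gaze_cv$all_conditions <- crossvalidate(feats, y6, config$cv_folds,
                                              config$fda_eps)
    }
  }

  # -- FRP / P100 ------------------------------------------------------
  peaks <- NULL; comparisons <- list()
  epochs <- extract_epochs(eeg, fixations$onset, config$epoch_window)
  note("epoching: %d epochs kept, %d rejected", dim(epochs$data)[3],
       epochs$n_rejected)
  if (dim(epochs$data)[3] >= config$min_template_epochs) {
    if (!is.null(bundle$scenes)) {
      epochs <- label_epochs(epochs, fixations, bundle$scenes,
                             bundle$events, config$fovea_radius,
                             config$color_threshold)
    }
    epochs <- bandpass_epochs(epochs, config$epoch_band)
    template <- build_reference(epochs, config$analysis_channel,
                                search_window = config$search_window,
                                min_epochs = config$min_template_epochs)
    regressors <- build_regressors(template, config$n_regressors,
                                   config$lat_jitter_ms, config$width_jitter)
    peaks <- fit_mlrd_all(epochs, regressors)
    if (!is.null(peaks$on_target)) {
      comparisons <- amplitude_comparisons(peaks)
    }
  } else {
    note("MLRd skipped: fewer than %d epochs", config$min_template_epochs)
  }

  # -- fixation-bound bandpower ---------------------------------------
  kp_times <- event_times(bundle$events, "keypress")
  has_kp <- vapply(seq_len(nrow(fixations)), function(i) {
    any(kp_times >= fixations$onset[i] & kp_times <= fixations$offset[i])
  }, TRUE)
  features <- bandpower_features(eeg, fixations, has_kp, config$bands)
  bandpower_cv <- NULL; durations <- NULL
  cls <- table(features$has_keypress)
  if (length(cls) == 2 && all(cls >= config$cv_folds)) {
    bandpower_cv <- classify_action_fixations(features, k = config$cv_folds,
                                              eps = config$fda_eps,
                                              repeats = config$cv_repeats)
    durations <- duration_stats(features$duration_ms, features$has_keypress)
    note("action classification: %.1f%% over %d folds",
         100 * bandpower_cv$mean_accuracy, config$cv_folds)
  } else {
    note("action classification skipped: class counts %s",
         paste(cls, collapse = "/"))
  }

  structure(list(sync = sync, fixations = fixations, metrics = metrics,
                 gaze_cv = gaze_cv, peaks = peaks,
                 comparisons = comparisons, bandpower_cv = bandpower_cv,
                 durations = durations, log = log, config = config),
            class = "frp_report")
}

# the four complementary category pairs of the amplitude analysis
amplitude_comparisons <- function(peaks) {
  p <- peaks[!is.na(peaks$n_objects) & peaks$n_objects >= 1, , drop = FALSE]
  out <- list()
  try_cmp <- function(a, b, labels) {
    if (length(a) >= 2 && length(b) >= 2) compare_groups(a, b, labels)
  }
  out$target <- try_cmp(p$amplitude[p$on_target],
                        p$amplitude[!p$on_target],
                        c("target", "non-target"))
  out$keypress <- try_cmp(p$amplitude[p$has_keypress],
                          p$amplitude[!p$has_keypress],
                          c("keypress", "no keypress"))
  out$objects <- try_cmp(p$amplitude[p$n_objects >= 2],
                         p$amplitude[p$n_objects == 1],
                         c("2+ objects", "1 object"))
  out$colors <- try_cmp(p$amplitude[p$n_colors >= 2],
                        p$amplitude[p$n_colors == 1],
                        c("2+ colors", "1 color"))
  out[!vapply(out, is.null, TRUE)]
}

# map fixation onsets to scene ids via the scene_on events
assign_scene <- function(onsets, events) {
  t_on <- event_times(events, "scene_on")
  ids <- vapply(events, function(e) {
    if (identical(e$type, "scene_on")) as.character(e$scene_id)
    else NA_character_
  }, "")
  ids <- ids[!is.na(ids)]
  if (!length(t_on)) return(rep(NA_character_, length(onsets)))
  idx <- findInterval(onsets, t_on)
  out <- rep(NA_character_, length(onsets))
  out[idx >= 1] <- ids[idx[idx >= 1]]
  out
}

#' @export
print.frp_report <- function(x, ...) {
  cat("<frp_report>\n")
  for (l in x$log) cat(" -", l, "\n")
  if (length(x$gaze_cv)) {
    cat(" gaze-metric classification:\n")
    for (nm in names(x$gaze_cv)) {
      cat(sprintf("   %s: %.1f%% (chance %.1f%%)\n", nm,
                  100 * x$gaze_cv[[nm]]$mean_accuracy,
                  100 * x$gaze_cv[[nm]]$chance_level))
    }
  }
  if (length(x$comparisons)) {
    cat(" amplitude comparisons:\n")
    for (cmp in x$comparisons) {
      cat(sprintf("   %s vs %s: p = %.3g [%s]\n", cmp$labels[1],
                  cmp$labels[2], cmp$p, cmp$star))
    }
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' @param report an `frp_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "frp_report"))
  strip <- function(x) {
    if (inherits(x, c("cv_result", "group_comparison", "duration_stats",
                      "sync_model"))) unclass(x)
    else if (is.list(x) && !is.data.frame(x)) lapply(x, strip)
    else x
  }
  out <- strip(report[c("sync", "metrics", "gaze_cv", "comparisons",
                        "bandpower_cv", "durations", "log")])
  out$peaks <- report$peaks
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
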