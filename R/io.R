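#' Write a recording bundle to a directory
#'
#' Serializes the three co-registered streams plus metadata as plain-text
#' files:
#' * `gaze.csv` — t_sec, eye, x_px, y_px, valid
#' * `eeg.tsv` — samples x channels matrix (µV), with `eeg_header.json`
#'   sidecar (fs_hz, channels, units, t0, n_samples)
#' * `events.jsonl` — one JSON object per line (t_sec, type, payload)
#' * `meta.json` — subject id, screen geometry, montage
#' * `truth.json`, `scenes.json` — ground truth and stimulus tables, when
#'   the bundle stems from the synthetic generator
#'
#' @param bundle a `recording_bundle` or `frp_session`.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  if (inherits(bundle, "frp_session")) bundle <- as_bundle(bundle)
  stopifnot(inherits(bundle, "recording_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)

  data.table::fwrite(bundle$gaze, file.path(path, "gaze.csv"))

  eeg <- bundle$eeg
  data.table::fwrite(as.data.table_safe(t(eeg$data)),
                     file.path(path, "eeg.tsv"), sep = "\t",
                     col.names = FALSE)
  jsonlite::write_json(list(fs_hz = eeg$fs, channels = eeg$channels,
                            units = eeg$units, t0 = eeg$t0,
                            n_samples = ncol(eeg$data)),
                       file.path(path, "eeg_header.json"),
                       auto_unbox = TRUE, digits = NA)

  lines <- vapply(bundle$events, function(e) {
    jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, file.path(path, "events.jsonl"))

  jsonlite::write_json(bundle$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(bundle$truth)) {
    jsonlite::write_json(bundle$truth, file.path(path, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(bundle$scenes)) {
    sc <- lapply(bundle$scenes, function(s) {
      list(scene_id = s$scene_id, object_count = s$object_count,
           color_similarity = s$color_similarity,
           missing_target = s$missing_target,
           target_shapes = s$target_shapes, search_shapes = s$search_shapes,
           screen = s$screen)
    })
    jsonlite::write_json(sc, file.path(path, "scenes.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

as.data.table_safe <- function(m) data.table::as.data.table(as.data.frame(m))

#' Convert a simulated session into a recording bundle
#'
#' @param session an `frp_session`.
#' @param subject subject identifier stored in the metadata.
#' @return a `recording_bundle`.
#' @export
as_bundle <- function(session, subject = "sim01") {
  stopifnot(inherits(session, "frp_session"))
  structure(list(
    eeg = session$eeg, gaze = session$gaze, events = session$events,
    meta = list(subject = subject, screen = default_screen(),
                montage = session$eeg$channels),
    truth = list(fixations = session$truth, clock = session$clock,
                 conditions = session$schedule$conditions),
    scenes = setNames(session$schedule$scenes,
                      vapply(session$schedule$scenes, `[[`, "", "scene_id"))
  ), class = "recording_bundle")
}

#' Read a recording bundle from a directory
#'
#' Validates stream presence, the EEG header/sample-count agreement, the
#' montage labels, and gaze timestamp ordering per eye.
#'
#' @param path directory written by [write_bundle()].
#' @return a `recording_bundle`.
#' @export
read_bundle <- function(path) {
  need <- c(gaze = "gaze.csv", eeg = "eeg.tsv", header = "eeg_header.json",
            events = "events.jsonl", meta = "meta.json")
  for (nm in names(need)) {
    if (!file.exists(file.path(path, need[[nm]]))) {
      stop("recording bundle is missing the ", nm, " stream (",
           need[[nm]], ")", call. = FALSE)
    }
  }
  gaze <- as.data.frame(data.table::fread(file.path(path, "gaze.csv")))
  for (eye in unique(gaze$eye)) {
    if (is.unsorted(gaze$t_sec[gaze$eye == eye])) {
      stop("gaze timestamps out of order for eye ", eye, call. = FALSE)
    }
  }

  hdr <- jsonlite::read_json(file.path(path, "eeg_header.json"),
                             simplifyVector = TRUE)
  known <- default_montage()
  bad <- setdiff(hdr$channels, known)
  if (length(bad)) {
    stop("unknown channel label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  mat <- t(as.matrix(data.table::fread(file.path(path, "eeg.tsv"),
                                       header = FALSE)))
  if (ncol(mat) != hdr$n_samples || nrow(mat) != length(hdr$channels)) {
    stop("EEG header/sample-count mismatch: header says ",
         length(hdr$channels), " x ", hdr$n_samples, ", file holds ",
         nrow(mat), " x ", ncol(mat), call. = FALSE)
  }
  rownames(mat) <- hdr$channels
  eeg <- structure(list(fs = hdr$fs_hz, channels = hdr$channels, data = mat,
                        t0 = hdr$t0, units = hdr$units),
                   class = "eeg_record")

  events <- lapply(readLines(file.path(path, "events.jsonl")),
                   jsonlite::fromJSON)
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)

  truth <- NULL
  if (file.exists(file.path(path, "truth.json"))) {
    truth <- jsonlite::read_json(file.path(path, "truth.json"),
                                 simplifyVector = TRUE)
  }
  scenes <- NULL
  if (file.exists(file.path(path, "scenes.json"))) {
    raw <- jsonlite::read_json(file.path(path, "scenes.json"),
                               simplifyVector = TRUE)
    scenes <- lapply(seq_len(nrow_or_len(raw)), function(i) {
      s <- if (is.data.frame(raw)) lapply(raw, `[[`, i) else raw[[i]]
      s$screen <- lapply(s$screen, unlist)
      structure(s, class = "frp_scene")
    })
    names(scenes) <- vapply(scenes, `[[`, "", "scene_id")
  }
  structure(list(eeg = eeg, gaze = gaze, events = events, meta = meta,
                 truth = truth, scenes = scenes),
            class = "recording_bundle")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)

#' @export
print.recording_bundle <- function(x, ...) {
  cat(sprintf("<recording_bundle> subject %s: %d gaze samples, %d x %d EEG, %d events\n",
              x$meta$subject, nrow(x$gaze), nrow(x$eeg$data),
              ncol(x$eeg$data), length(x$events)))
  invisible(x)
}
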