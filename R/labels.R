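#' Foveal content at a gaze position
#'
#' Counts the shapes whose centers fall within the foveal region (a circle
#' of `fovea_radius` px, ~80 px at the study's 80 cm viewing distance)
#' around a fixation centroid, and groups their colors: two shapes count as
#' differently colored when their weighted RGB distance
#' ([color_distance()]) exceeds `color_threshold` (default 200).
#'
#' @param scene an `frp_scene`.
#' @param centroid numeric (x, y) in screen px.
#' @param fovea_radius foveal radius in px.
#' @param color_threshold distance above which two colors differ.
#' @return list with `n_objects`, `n_colors`, `on_target`.
#' @export
foveal_content <- function(scene, centroid, fovea_radius = 80,
                           color_threshold = 200) {
  shapes <- rbind(scene$target_shapes, scene$search_shapes)
  d <- sqrt((shapes$x - centroid[1])^2 + (shapes$y - centroid[2])^2)
  fov <- shapes[d <= fovea_radius, , drop = FALSE]
  n_objects <- nrow(fov)
  if (n_objects == 0L) {
    return(list(n_objects = 0L, n_colors = 0L, on_target = FALSE))
  }
  # greedy color grouping: join the first group whose representative is
  # within the similarity threshold
  reps <- list()
  for (i in seq_len(n_objects)) {
    col <- c(fov$r[i], fov$g[i], fov$b[i])
    hit <- FALSE
    for (rep_col in reps) {
      if (color_distance(col, rep_col) <= color_threshold) { hit <- TRUE; break }
    }
    if (!hit) reps[[length(reps) + 1L]] <- col
  }
  list(n_objects = n_objects, n_colors = length(reps),
       on_target = any(fov$is_target))
}
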