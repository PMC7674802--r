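#' @name scene
#' @title Synthetic visual-search scenes
#'
#' @description
#' Scenes emulate a two-panel visual search display on a 1920 x 1080 screen:
#' a small target panel on the left holding 3--5 non-overlapping shapes, and a
#' larger search panel on the right holding the target shapes plus distractors.
#' Scenes come in a 2 x 3 condition grid: object count (`few`/`many`
#' distractors) crossed with target-vs-distractor color similarity
#' (`high`/`medium`/`low` under the weighted RGB distance of
#' [color_distance()]). Shape centers keep a minimum pairwise Euclidean
#' distance of 100 px (`many`) or 170 px (`few`); target-panel bounding boxes
#' may not intersect.
#'
#' All generation uses R's global RNG; call `set.seed()` for reproducibility.
NULL

.shape_kinds <- c("square", "circle", "triangle", "half-moon", "arrow",
                  "cross", "star", "diamond")

default_screen <- function() {
  list(
    width = 1920L, height = 1080L,
    # left panel shows the targets, right panel is searched
    target_region = c(xmin = 0L, ymin = 0L, xmax = 480L, ymax = 1080L),
    search_region = c(xmin = 480L, ymin = 0L, xmax = 1920L, ymax = 1080L)
  )
}

object_count_levels <- c("few", "many")
color_similarity_levels <- c("high", "medium", "low")

#' All six scene conditions
#'
#' @return data.frame with columns `object_count` and `color_similarity`,
#'   one row per condition (6 rows).
#' @export
scene_conditions <- function() {
  expand.grid(object_count = object_count_levels,
              color_similarity = color_similarity_levels,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

new_shape <- function(shape_id, kind, color, x, y, bbox_size, rotation,
                      is_target) {
  data.frame(shape_id = shape_id, kind = kind,
             r = color[1], g = color[2], b = color[3],
             x = x, y = y, bbox_size = bbox_size, rotation = rotation,
             is_target = is_target, stringsAsFactors = FALSE)
}

# Rejection placement of n points in region with min pairwise distance.
place_centers <- function(n, region, min_dist, margin, max_attempts = 20000L) {
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L
  while (length(xs) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("scene generation: could not place ", n, " shape centers at ",
           min_dist, " px spacing", call. = FALSE)
    }
    x <- stats::runif(1, region["xmin"] + margin, region["xmax"] - margin)
    y <- stats::runif(1, region["ymin"] + margin, region["ymax"] - margin)
    if (length(xs) == 0 || all(sqrt((xs - x)^2 + (ys - y)^2) >= min_dist)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  cbind(x = xs, y = ys)
}

#' Generate one synthetic scene
#'
#' @param object_count `"few"` or `"many"` distractors in the search panel
#'   (defaults draw 12--18 or 30--45 respectively).
#' @param color_similarity `"high"`, `"medium"` or `"low"`: the class of the
#'   weighted RGB distance between the scene's target color and every
#'   distractor color.
#' @param missing_target if `TRUE` one target shape is absent from the
#'   search panel (the vigilance manipulation).
#' @param bbox_size fixed shape bounding-box side length in px.
#' @param screen screen geometry, see `default_screen()`.
#' @return object of class `"frp_scene"`: list with `scene_id`, condition
#'   labels, `target_shapes` and `search_shapes` data frames, `missing_target`
#'   and `screen`.
#' @export
generate_scene <- function(object_count = c("few", "many"),
                           color_similarity = c("high", "medium", "low"),
                           missing_target = FALSE,
                           bbox_size = 60,
                           screen = default_screen()) {
  object_count <- match.arg(object_count)
  color_similarity <- match.arg(color_similarity)

  min_dist <- if (object_count == "many") 100 else 170
  n_search_extra <- if (object_count == "many") {
    sample(30:45, 1)
  } else {
    sample(12:18, 1)
  }
  n_targets <- sample(3:5, 1)

  # one scene-level target color, drawn so the similarity class is
  # attainable (a mid-gray target cannot reach the low-similarity range);
  # each distractor color is kept in-class relative to it
  target_color <- sample_color_pair(color_similarity)$a

  # target panel: non-overlapping axis-aligned boxes
  tc <- place_centers(n_targets, screen$target_region,
                      min_dist = bbox_size * sqrt(2), margin = bbox_size)
  target_shapes <- do.call(rbind, lapply(seq_len(n_targets), function(i) {
    new_shape(sprintf("T%02d", i), sample(.shape_kinds, 1), target_color,
              tc[i, "x"], tc[i, "y"], bbox_size, stats::runif(1, 0, 360),
              is_target = TRUE)
  }))

  # search panel: target copies first, then distractors
  n_targets_in_search <- if (missing_target) n_targets - 1L else n_targets
  n_search <- n_targets_in_search + n_search_extra
  sc <- place_centers(n_search, screen$search_region,
                      min_dist = min_dist, margin = bbox_size / 2)
  rows <- vector("list", n_search)
  for (i in seq_len(n_search)) {
    if (i <= n_targets_in_search) {
      rows[[i]] <- new_shape(sprintf("S%02d", i), target_shapes$kind[i],
                             target_color, sc[i, "x"], sc[i, "y"], bbox_size,
                             stats::runif(1, 0, 360), is_target = TRUE)
    } else {
      col <- distractor_color(target_color, color_similarity)
      rows[[i]] <- new_shape(sprintf("S%02d", i), sample(.shape_kinds, 1),
                             col, sc[i, "x"], sc[i, "y"], bbox_size,
                             stats::runif(1, 0, 360), is_target = FALSE)
    }
  }
  search_shapes <- do.call(rbind, rows)

  structure(list(
    scene_id = NA_character_,
    object_count = object_count,
    color_similarity = color_similarity,
    target_color = target_color,
    target_shapes = target_shapes,
    search_shapes = search_shapes,
    missing_target = missing_target,
    screen = screen
  ), class = "frp_scene")
}

# draw a distractor color whose distance to `ref` lies in the class range
distractor_color <- function(ref, level, max_attempts = 10000L) {
  rng <- .color_ranges[[level]]
  closed_top <- identical(level, "low")
  for (i in seq_len(max_attempts)) {
    b <- sample_color_near(ref, rng)
    d <- color_distance(ref, b)
    if (d >= rng[1] && (d < rng[2] || (closed_top && d <= rng[2]))) return(b)
  }
  stop("distractor_color: rejection sampling exhausted", call. = FALSE)
}

#' @export
print.frp_scene <- function(x, ...) {
  cat(sprintf("<frp_scene %s> %s objects / %s color similarity\n",
              x$scene_id, x$object_count, x$color_similarity))
  cat(sprintf("  %d target shapes, %d search-panel shapes%s\n",
              nrow(x$target_shapes), nrow(x$search_shapes),
              if (x$missing_target) " (one target missing)" else ""))
  invisible(x)
}

#' Generate a balanced session schedule
#'
#' Builds `n_per_condition` scenes for each of the six conditions, flags
#' `round(missing_rate * N)` of them as missing-target (seeded sampling
#' without replacement), and orders the scenes by a seeded random
#' permutation. The study design uses 23 scenes per condition (138 total)
#' with an 8% missing rate.
#'
#' @param n_per_condition scenes per condition (>= 1).
#' @param missing_rate fraction of scenes with a missing target, in [0, 1).
#' @param ... passed to [generate_scene()].
#' @return object of class `"frp_schedule"`: list with `scenes` (ordered
#'   list of `frp_scene`) and a `conditions` data.frame (scene_id, condition
#'   labels, missing flag).
#' @export
generate_schedule <- function(n_per_condition = 23, missing_rate = 0.08, ...) {
  stopifnot(n_per_condition >= 1, missing_rate >= 0, missing_rate < 1)
  cond <- scene_conditions()
  total <- 6L * as.integer(n_per_condition)
  layout <- cond[rep(seq_len(6L), each = n_per_condition), , drop = FALSE]
  n_missing <- round(missing_rate * total)
  missing <- logical(total)
  if (n_missing > 0) missing[sample.int(total, n_missing)] <- TRUE
  ord <- sample.int(total)
  layout <- layout[ord, , drop = FALSE]
  missing <- missing[ord]

  scenes <- vector("list", total)
  for (i in seq_len(total)) {
    sc <- generate_scene(object_count = layout$object_count[i],
                         color_similarity = layout$color_similarity[i],
                         missing_target = missing[i], ...)
    sc$scene_id <- sprintf("scene%03d", i)
    scenes[[i]] <- sc
  }
  structure(list(
    scenes = scenes,
    conditions = data.frame(
      scene_id = vapply(scenes, `[[`, "", "scene_id"),
      object_count = layout$object_count,
      color_similarity = layout$color_similarity,
      missing_target = missing,
      stringsAsFactors = FALSE
    ),
    n_per_condition = as.integer(n_per_condition),
    missing_rate = missing_rate
  ), class = "frp_schedule")
}

#' @export
print.frp_schedule <- function(x, ...) {
  cat(sprintf("<frp_schedule> %d scenes (%d per condition), %d missing-target\n",
              length(x$scenes), x$n_per_condition,
              sum(x$conditions$missing_target)))
  invisible(x)
}
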