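min_pair_dist <- function(shapes) {
  d <- as.matrix(dist(cbind(shapes$x, shapes$y)))
  min(d[upper.tri(d)])
}

test_that("scenes respect spacing, counts, and color-class invariants", {
  set.seed(21)
  for (oc in c("few", "many")) {
    for (cs in c("high", "medium", "low")) {
      sc <- generate_scene(oc, cs)
      nt <- nrow(sc$target_shapes)
      expect_gte(nt, 3); expect_lte(nt, 5)
      expect_gte(min_pair_dist(sc$search_shapes),
                 if (oc == "many") 100 else 170)
      # target-panel bounding boxes must not intersect
      ts <- sc$target_shapes
      for (i in seq_len(nt - 1)) for (j in (i + 1):nt) {
        expect_true(abs(ts$x[i] - ts$x[j]) >= ts$bbox_size[i] ||
                    abs(ts$y[i] - ts$y[j]) >= ts$bbox_size[i])
      }
      # distractor colors in the declared class relative to the target color
      dis <- sc$search_shapes[!sc$search_shapes$is_target, ]
      dd <- vapply(seq_len(nrow(dis)), function(k) {
        color_distance(sc$target_color, c(dis$r[k], dis$g[k], dis$b[k]))
      }, 0)
      expect_true(all(vapply(dd, color_similarity_class, "") == cs))
      # shapes stay inside their panels
      expect_true(all(sc$search_shapes$x >= sc$screen$search_region["xmin"]))
      expect_true(all(sc$target_shapes$x <= sc$screen$target_region["xmax"]))
    }
  }
})

test_that("distractor counts follow the object-count level", {
  set.seed(22)
  few <- sum(!generate_scene("few", "high")$search_shapes$is_target)
  many <- sum(!generate_scene("many", "high")$search_shapes$is_target)
  expect_gte(few, 12); expect_lte(few, 18)
  expect_gte(many, 30); expect_lte(many, 45)
})

test_that("schedules are exactly balanced with the study counts", {
  set.seed(23)
  sch <- generate_schedule(23, 0.08)
  expect_length(sch$scenes, 138)
  counts <- table(sch$conditions$object_count, sch$conditions$color_similarity)
  expect_true(all(counts == 23))
  expect_identical(sum(sch$conditions$missing_target), 11L)  # round(0.08*138)

  small <- generate_schedule(1, 0)
  expect_length(small$scenes, 6)
  expect_identical(sum(small$conditions$missing_target), 0L)
})

test_that("schedule order is a seed-reproducible permutation", {
  set.seed(24); a <- generate_schedule(2, 0.08)
  set.seed(24); b <- generate_schedule(2, 0.08)
  expect_identical(a$conditions, b$conditions)
  set.seed(25); c <- generate_schedule(2, 0.08)
  expect_false(identical(a$conditions$object_count,
                         c$conditions$object_count) &&
               identical(a$conditions$color_similarity,
                         c$conditions$color_similarity))
})

test_that("missing-target scenes drop one target from the search panel", {
  set.seed(26)
  sc <- generate_scene("few", "high", missing_target = TRUE)
  expect_identical(sum(sc$search_shapes$is_target),
                   nrow(sc$target_shapes) - 1L)
})
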