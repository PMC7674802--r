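fx_table <- function(x, y, dur_ms) {
  data.frame(x = x, y = y, duration = dur_ms / 1000)
}

test_that("gaze metrics match hand-computed values", {
  # all fixations long
  fx <- fx_table(c(0, 200, 400), c(0, 0, 0), c(300, 300, 300))
  m <- compute_gaze_metrics(fx)
  expect_equal(unname(m["m1"]), 1)
  # consecutive centroids 200 px apart: every movement is distant
  expect_equal(unname(m["m2"]), 1)
  expect_equal(unname(m["m3"]), 0)

  # two fixations at the same location: the second is a revisit
  fx2 <- fx_table(c(100, 100), c(100, 100), c(200, 300))
  m2 <- compute_gaze_metrics(fx2)
  expect_equal(unname(m2["m3"]), 0.5)
  expect_equal(unname(m2["m2"]), 0)     # landing inside the foveal region
  expect_equal(unname(m2["m1"]), 0.5)   # 300 ms > 250 ms, 200 ms is not

  # revisit counted once even when within range of several prior fixations
  fx3 <- fx_table(c(0, 50, 25, 500), c(0, 0, 0, 0), rep(300, 4))
  m3 <- compute_gaze_metrics(fx3)
  expect_equal(unname(m3["m3"]), 0.5)   # 2nd and 3rd revisit, 4th does not
})

test_that("metrics are undefined below two fixations", {
  expect_error(compute_gaze_metrics(fx_table(1, 1, 300)), "fewer than 2")
})

test_that("metrics are invariant to time rescaling except through M1", {
  set.seed(71)
  fx <- fx_table(runif(20, 0, 1900), runif(20, 0, 1000),
                 runif(20, 120, 500))
  m <- compute_gaze_metrics(fx)
  # halve all durations: spatial metrics unchanged, M1 responds
  fx2 <- fx; fx2$duration <- fx$duration / 2
  m2 <- compute_gaze_metrics(fx2)
  expect_equal(m2[c("m2", "m3")], m[c("m2", "m3")])
  expect_lte(m2[["m1"]], m[["m1"]])
  # rescaling positions uniformly can only change the spatial metrics
  fx3 <- fx; fx3$x <- fx$x * 3; fx3$y <- fx$y * 3
  m3 <- compute_gaze_metrics(fx3)
  expect_equal(m3[["m1"]], m[["m1"]])
})

test_that("default-generator metrics discriminate object count above chance", {
  set.seed(73)
  sch <- generate_schedule(12, 0)
  metr <- do.call(rbind, lapply(seq_along(sch$scenes), function(i) {
    fx <- detect_fixations(simulate_gaze(sch$scenes[[i]])$gaze)
    m <- compute_gaze_metrics(fx)
    data.frame(m1 = m[["m1"]], m2 = m[["m2"]], m3 = m[["m3"]],
               object_count = sch$conditions$object_count[i])
  }))
  cv <- crossvalidate(as.matrix(metr[, 1:3]), metr$object_count,
                      k = 5, repeats = 5)
  se <- max(cv$sd_accuracy / sqrt(length(cv$fold_accuracies)), 0.01)
  expect_gt(cv$mean_accuracy, 0.5 + 3 * se)
})

test_that("per-scene metrics join condition labels", {
  set.seed(72)
  fx <- rbind(
    cbind(fx_table(c(0, 300, 600), c(0, 0, 0), c(300, 200, 300)),
          scene_id = "s1"),
    cbind(fx_table(c(0, 10), c(0, 0), c(200, 200)), scene_id = "s2"),
    cbind(fx_table(500, 500, 300), scene_id = "s3")  # dropped: 1 fixation
  )
  cond <- data.frame(scene_id = c("s1", "s2", "s3"),
                     object_count = c("few", "many", "few"))
  res <- session_gaze_metrics(fx, cond)
  expect_identical(nrow(res), 2L)
  expect_identical(res$object_count, c("few", "many"))
  expect_true(all(res$m1 >= 0 & res$m1 <= 1))
})
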