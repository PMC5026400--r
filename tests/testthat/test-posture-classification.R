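make_frames <- function(p, r, a, step = 2) {
  n <- length(p)
  structure(data.frame(frame = 1:n, start_s = (0:(n - 1)) * step,
                       end_s = (1:n) * step, p = p, r = r, a = a,
                       gx = 0, gy = 0, gz = 1, m1 = 1, m2 = 1),
            class = c("feature_frames", "data.frame"), frame_step_s = step)
}

## well-separated two-posture data: standing-like vs sitting-like
separable_set <- function(n_per, id, seed) {
  set.seed(seed)
  data.frame(
    animal_id = id,
    p = c(stats::rnorm(n_per, 0, 2), stats::rnorm(n_per, 60, 2)),
    r = stats::rnorm(2 * n_per, 0, 2),
    a = c(stats::rnorm(n_per, 0.08, 0.01), stats::rnorm(n_per, 0.02, 0.005)),
    label = factor(rep(c("ST", "S"), each = n_per),
                   levels = posture_classes()))
}

test_that("frames are labelled by midpoint with half-open intervals", {
  fr <- make_frames(p = rep(0, 10), r = rep(0, 10), a = rep(0.01, 10))
  ## one interval covering everything
  track <- annotation_track("a", data.frame(start_s = 0, end_s = 20,
                                            label = "LL"), data.frame())
  lf <- label_frames(fr, track)
  expect_equal(nrow(lf), 10L)
  expect_true(all(lf$label == "LL"))

  ## frames with midpoint inside a transition interval are excluded
  track2 <- annotation_track(
    "a", data.frame(start_s = c(0, 8), end_s = c(4, 20),
                    label = c("ST", "LL")),
    data.frame(start_s = 4, end_s = 8))
  lf2 <- label_frames(fr, track2)
  ## frames 3 and 4 (midpoints 5, 7) fall in the transition
  expect_equal(nrow(lf2), 8L)
  expect_false(any(lf2$start_s %in% c(4, 6)))

  ## boundary midpoint belongs to the interval that starts there
  fr3 <- make_frames(p = rep(0, 2), r = rep(0, 2), a = rep(0.01, 2),
                     step = 2)
  ## midpoints at 1 and 3; intervals [0,1) and [1,6): midpoint 1 -> second
  track3 <- annotation_track(
    "a", data.frame(start_s = c(0, 1), end_s = c(1, 6),
                    label = c("ST", "SL")), data.frame())
  lf3 <- label_frames(fr3, track3)
  expect_equal(as.character(lf3$label), c("SL", "SL"))

  ## uncovered frames are dropped with a count warning
  track4 <- annotation_track("a", data.frame(start_s = 0, end_s = 10,
                                             label = "RL"), data.frame())
  expect_warning(lf4 <- label_frames(fr, track4), "5 frame")
  expect_equal(nrow(lf4), 5L)
})

test_that("training separates constructed classes and is deterministic", {
  d <- separable_set(60, "a", seed = 11)
  m <- train_posture_model(d, seed = 11)
  pr <- predict(m, d)
  conf <- frame_confusion(d$label, pr)
  expect_equal(conf$mean_f1, 1.0)  # separable by construction

  ## identical seed, identical selection; model predicts identically
  m2 <- train_posture_model(d, seed = 11)
  expect_identical(m$best, m2$best)
  expect_equal(m$cv_results$score, m2$cv_results$score)
  expect_identical(predict(m2, d), pr)

  ## single-class training set is rejected
  expect_error(train_posture_model(d[d$label == "ST", ], seed = 1),
               class = "sowmotion_training_error")
})

test_that("prediction honours the closed five-class world", {
  d <- separable_set(40, "a", seed = 5)
  m <- train_posture_model(d, seed = 1)
  pr <- predict(m, d)
  expect_s3_class(pr, "factor")
  expect_identical(levels(pr), posture_classes())
  ## empty input gives an empty factor
  expect_length(predict(m, d[0, ]), 0L)
  ## missing feature columns are a format error
  expect_error(predict(m, data.frame(p = 1, r = 2)),
               class = "sowmotion_format_error")
  ## frames identical to a training exemplar of a separable class recover it
  exemplar <- d[d$label == "S", ][1, ]
  expect_identical(as.character(predict(m, exemplar)), "S")
})

test_that("standardization and tuning use training data only", {
  d_train <- separable_set(50, "a", seed = 2)
  m1 <- train_posture_model(d_train, seed = 3)
  ## the fitted model is a function of the training set and seed alone:
  ## refitting after unrelated data has changed is bit-identical
  unrelated <- separable_set(50, "b", seed = 99)
  unrelated$p <- unrelated$p + 1000
  m2 <- train_posture_model(d_train, seed = 3)
  expect_identical(m1$center, m2$center)
  expect_identical(m1$scale, m2$scale)
  expect_identical(m1$best, m2$best)
  expect_equal(m1$svm$SV, m2$svm$SV)
})

test_that("leave-one-pig-out folds each animal exactly once and pools results", {
  sets <- lapply(1:3, function(i) separable_set(40, paste0("sow", i),
                                                seed = 30 + i))
  names(sets) <- paste0("sow", 1:3)
  ev <- lopo_evaluate(sets, seed = 1)
  ## separable geometry: perfect pooled classification
  expect_equal(ev$mean_f1, 1.0)
  expect_true(all(ev$confusion[cbind(c("ST", "S"), c("ST", "S"))] > 0))
  expect_equal(sum(ev$confusion), sum(vapply(sets, nrow, 1L)))

  ## each animal tested exactly once
  tested <- table(ev$predictions$animal_id)
  expect_identical(sort(names(tested)), sort(names(sets)))
  expect_equal(as.numeric(tested), vapply(sets, nrow, 1L),
               ignore_attr = TRUE)

  ## confusion-matrix row sums equal per-class pooled frame counts
  pooled <- do.call(rbind, sets)
  expect_equal(as.numeric(rowSums(ev$confusion)),
               as.numeric(table(factor(pooled$label,
                                       levels = posture_classes()))))

  expect_error(lopo_evaluate(sets[1], seed = 1),
               class = "sowmotion_training_error")
})
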