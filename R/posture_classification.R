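## RBF-kernel SVM mapping the per-frame feature triple {p, r, a} to the five
## posture classes, with grid-searched hyper-parameters and
## leave-one-pig-out evaluation.

#' Label feature frames from an annotation track
#'
#' Each frame is labelled with the posture interval containing its midpoint,
#' using the half-open convention `[start, end)` so a midpoint landing
#' exactly on a boundary belongs to the interval that starts there. Frames
#' whose midpoint falls inside an annotated transition interval are excluded
#' (they belong to no posture state); frames covered by neither track are
#' dropped with a count warning.
#'
#' @param frames A `feature_frames` data frame from [extract_features()].
#' @param track An [annotation_track()].
#' @return Data frame of class `labelled_frames`: columns `animal_id`,
#'   `start_s`, `end_s`, `p`, `r`, `a`, `label` (factor over
#'   [posture_classes()]).
#' @export
label_frames <- function(frames, track) {
  stopifnot(inherits(track, "annotation_track"))
  mid <- (frames$start_s + frames$end_s) / 2
  lab <- rep(NA_character_, length(mid))
  pos <- track$postures
  if (nrow(pos) > 0L) {
    for (i in seq_len(nrow(pos)))
      lab[mid >= pos$start_s[i] & mid < pos$end_s[i]] <- pos$label[i]
  }
  in_trans <- rep(FALSE, length(mid))
  tra <- track$transitions
  if (nrow(tra) > 0L) {
    for (i in seq_len(nrow(tra)))
      in_trans <- in_trans | (mid >= tra$start_s[i] & mid < tra$end_s[i])
  }
  uncovered <- sum(is.na(lab) & !in_trans)
  if (uncovered > 0L)
    warning(sprintf("%d frame(s) uncovered by any annotation dropped",
                    uncovered), call. = FALSE)
  keep <- !is.na(lab) & !in_trans
  out <- data.frame(animal_id = track$animal_id,
                    start_s = frames$start_s[keep],
                    end_s = frames$end_s[keep],
                    p = frames$p[keep], r = frames$r[keep],
                    a = frames$a[keep],
                    label = factor(lab[keep], levels = .POSTURES))
  structure(out, class = c("labelled_frames", "data.frame"))
}

default_svm_grid <- function() {
  list(cost = c(0.1, 1, 10, 100), gamma = c(0.01, 0.1, 1, 10))
}

## stratified subsample of row indices, at most k per class
subsample_by_class <- function(labels, k) {
  unlist(lapply(split(seq_along(labels), labels), function(idx) {
    if (length(idx) <= k) idx else sort(sample(idx, k))
  }), use.names = FALSE)
}

macro_f1_from_table <- function(tab) {
  tp <- diag(tab)
  f1 <- 2 * tp / (2 * tp + (colSums(tab) - tp) + (rowSums(tab) - tp))
  mean(f1, na.rm = TRUE)
}

#' Train the RBF-SVM posture classifier
#'
#' Fits a radial-basis-function support vector machine on standardized
#' `{p, r, a}` features. Hyper-parameters (`cost`, `gamma`) are selected by
#' grid search with stratified internal cross-validation on the training set
#' only, scored by macro-averaged F1; standardization statistics likewise
#' come from the training data only, so nothing about held-out animals leaks
#' into the model. The whole procedure is deterministic given `seed`.
#'
#' Because RBF-SVM training cost grows superlinearly in the number of
#' frames, the grid search runs on a stratified subsample of at most
#' `tune_max_per_class` frames per class and the final fit on at most
#' `fit_max_per_class`; raise the caps for small data sets if exact full-data
#' fits are wanted.
#'
#' @param data A `labelled_frames` data frame (columns `p`, `r`, `a`,
#'   `label`). At least two classes, each with at least 10 frames, must be
#'   present.
#' @param grid Named list with numeric vectors `cost` and `gamma`.
#' @param seed Integer seed controlling fold assignment and subsampling.
#' @param cv_folds Internal cross-validation folds for the grid search.
#' @param tune_max_per_class,fit_max_per_class Per-class frame caps for the
#'   grid search and the final fit.
#' @param class_weights If `TRUE`, weight classes inversely to their
#'   training frequency (off by default).
#' @return An object of class `posture_model`.
#' @export
train_posture_model <- function(data, grid = default_svm_grid(), seed = 1,
                                cv_folds = 3, tune_max_per_class = 400,
                                fit_max_per_class = 2000,
                                class_weights = FALSE) {
  lab <- factor(data$label, levels = .POSTURES)
  lab <- droplevels(lab)
  counts <- table(lab)
  if (length(counts) < 2L)
    stop_sowmotion("training set must contain at least 2 classes",
                   "sowmotion_training_error")
  if (any(counts < 10L))
    warning(sprintf("class(es) with fewer than 10 frames: %s",
                    paste(names(counts)[counts < 10L], collapse = ", ")),
            call. = FALSE)
  feats <- as.matrix(data[, c("p", "r", "a")])
  centre <- colMeans(feats)
  scl <- apply(feats, 2L, stats::sd)
  scl[scl == 0] <- 1
  fs <- scale(feats, center = centre, scale = scl)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  tune_idx <- subsample_by_class(lab, tune_max_per_class)
  tl <- droplevels(lab[tune_idx])
  tf <- fs[tune_idx, , drop = FALSE]
  ## internal CV folds: grouped by animal when possible, so the grid search
  ## scores generalization to unseen animals (as the model will be used),
  ## not interpolation within animals it has already seen
  anim <- if ("animal_id" %in% names(data))
    as.character(data$animal_id[tune_idx]) else NULL
  fold <- integer(length(tl))
  if (!is.null(anim) && length(unique(anim)) >= cv_folds) {
    ua <- unique(anim)
    afold <- sample(rep_len(seq_len(cv_folds), length(ua)))
    fold <- afold[match(anim, ua)]
  } else {
    for (idx in split(seq_along(tl), tl))
      fold[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }

  combos <- expand.grid(cost = grid$cost, gamma = grid$gamma,
                        KEEP.OUT.ATTRS = FALSE)
  combos$score <- NA_real_
  for (i in seq_len(nrow(combos))) {
    sc <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      if (nlevels(droplevels(tl[tr])) < 2L) { sc[f] <- NA; next }
      fit <- e1071::svm(tf[tr, , drop = FALSE], droplevels(tl[tr]),
                        kernel = "radial", cost = combos$cost[i],
                        gamma = combos$gamma[i], scale = FALSE)
      pr <- stats::predict(fit, tf[!tr, , drop = FALSE])
      tab <- table(factor(tl[!tr], levels = levels(tl)),
                   factor(pr, levels = levels(tl)))
      sc[f] <- macro_f1_from_table(tab)
    }
    combos$score[i] <- mean(sc, na.rm = TRUE)
  }
  best <- combos[which.max(combos$score), ]  # first maximum: deterministic

  fit_idx <- subsample_by_class(lab, fit_max_per_class)
  cw <- NULL
  if (isTRUE(class_weights)) {
    tabf <- table(droplevels(lab[fit_idx]))
    cw <- as.numeric(sum(tabf) / (length(tabf) * tabf))
    names(cw) <- names(tabf)
  }
  final <- e1071::svm(fs[fit_idx, , drop = FALSE],
                      droplevels(lab[fit_idx]),
                      kernel = "radial", cost = best$cost, gamma = best$gamma,
                      scale = FALSE, class.weights = cw)
  structure(list(svm = final, center = centre, scale = scl,
                 best = list(cost = best$cost, gamma = best$gamma),
                 cv_results = combos, class_counts = counts,
                 seed = seed),
            class = "posture_model")
}

#' @export
print.posture_model <- function(x, ...) {
  cat("<posture_model> RBF-SVM on standardized {p, r, a}\n")
  cat(sprintf("  selected cost = %g, gamma = %g (grid of %d combinations)\n",
              x$best$cost, x$best$gamma, nrow(x$cv_results)))
  cat("  training frames per class:\n")
  print(x$class_counts)
  invisible(x)
}

#' Predict posture classes for feature frames
#'
#' @param object A fitted [train_posture_model()] model.
#' @param newdata Data frame (or matrix) with columns `p`, `r`, `a`.
#' @param ... Unused.
#' @return Factor of predicted labels over [posture_classes()], one per
#'   frame (empty input gives an empty factor).
#' @export
predict.posture_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (!all(c("p", "r", "a") %in% names(newdata)))
    stop_sowmotion("newdata must have columns p, r, a",
                   "sowmotion_format_error")
  if (nrow(newdata) == 0L) return(factor(character(), levels = .POSTURES))
  fs <- scale(as.matrix(newdata[, c("p", "r", "a")]),
              center = object$center, scale = object$scale)
  pr <- stats::predict(object$svm, fs)
  factor(as.character(pr), levels = .POSTURES)
}

#' Leave-one-pig-out evaluation of the posture classifier
#'
#' One cross-validation fold per animal: the classifier is trained on all
#' other animals and tested on the held-out one. Predictions from all folds
#' are pooled and per-class F1 scores are computed from the pooled confusion
#' matrix (rows = true class, columns = predicted).
#'
#' @param frame_sets Named list of `labelled_frames`, one per animal, or a
#'   single `labelled_frames` data frame with an `animal_id` column.
#' @param grid,seed,... Passed to [train_posture_model()].
#' @return An object of class `lopo_eval`: `confusion` (5x5 table),
#'   `per_class_f1`, `mean_f1`, and the pooled `predictions` data frame.
#' @export
lopo_evaluate <- function(frame_sets, grid = default_svm_grid(), seed = 1,
                          ...) {
  if (is.data.frame(frame_sets))
    frame_sets <- split(frame_sets, frame_sets$animal_id)
  if (length(frame_sets) < 2L)
    stop_sowmotion("leave-one-pig-out needs at least 2 animals",
                   "sowmotion_training_error")
  ids <- names(frame_sets)
  if (is.null(ids)) ids <- as.character(seq_along(frame_sets))
  preds <- vector("list", length(frame_sets))
  for (k in seq_along(frame_sets)) {
    train_df <- do.call(rbind, frame_sets[-k])
    test_df <- frame_sets[[k]]
    present <- table(factor(train_df$label, levels = .POSTURES))
    missing <- names(present)[present == 0L &
                                table(factor(test_df$label,
                                             levels = .POSTURES)) > 0L]
    if (length(missing) > 0L)
      warning(sprintf("fold %s: class(es) absent from training data: %s",
                      ids[k], paste(missing, collapse = ", ")),
              call. = FALSE)
    model <- train_posture_model(train_df, grid = grid, seed = seed, ...)
    preds[[k]] <- data.frame(
      animal_id = ids[k],
      truth = factor(test_df$label, levels = .POSTURES),
      predicted = predict(model, test_df))
  }
  pooled <- do.call(rbind, preds)
  conf <- frame_confusion(pooled$truth, pooled$predicted)
  structure(list(confusion = conf$confusion,
                 per_class_f1 = conf$per_class_f1,
                 mean_f1 = conf$mean_f1,
                 predictions = pooled, animals = ids),
            class = "lopo_eval")
}

#' @export
print.lopo_eval <- function(x, ...) {
  cat(sprintf("<lopo_eval> %d animals, %d pooled test frames\n",
              length(x$animals), nrow(x$predictions)))
  cat("per-class F1:\n")
  print(round(x$per_class_f1, 3))
  cat(sprintf("mean F1: %.3f\n", x$mean_f1))
  invisible(x)
}
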