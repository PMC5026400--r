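## Event-based matching of detected vs annotated transitions, the
## precision/recall/F1 metrics, and frame-level confusion matrices.

#' Match detected transitions against annotated transition intervals
#'
#' A detection *coincides* with an annotation when their intervals overlap
#' after the annotation has been dilated by `tolerance_s` on each side (the
#' dilation absorbs sensor/video clock-synchronization error; the default
#' 2 s is one base frame). Each annotation with at least one coinciding
#' detection contributes exactly one true positive — multiple detections on
#' the same annotation still count as a single correct result — annotations
#' with none contribute one false negative each, and detections coinciding
#' with no annotation contribute one false positive each.
#'
#' @param detected Data frame with columns `start_s`, `end_s` (e.g. from
#'   [detect_and_segment()]), time-sorted by `start_s`.
#' @param annotated Data frame with columns `start_s`, `end_s`, or an
#'   [annotation_track()] (its transition intervals are used), time-sorted.
#' @param tolerance_s Non-negative dilation in seconds.
#' @return An object of class `event_counts`: integers `tp`, `fp`, `fn`,
#'   with `tp + fn` equal to the number of annotated events.
#' @export
match_events <- function(detected, annotated, tolerance_s = 2) {
  if (inherits(annotated, "annotation_track")) annotated <- annotated$transitions
  detected <- as.data.frame(detected)
  annotated <- as.data.frame(annotated)
  if (!is_scalar_num(tolerance_s) || tolerance_s < 0)
    stop_sowmotion("tolerance_s must be non-negative",
                   "sowmotion_config_error")
  if (nrow(detected) > 1L && is.unsorted(detected$start_s))
    stop_sowmotion("detected events must be time-sorted",
                   "sowmotion_format_error")
  if (nrow(annotated) > 1L && is.unsorted(annotated$start_s))
    stop_sowmotion("annotated events must be time-sorted",
                   "sowmotion_format_error")
  nd <- nrow(detected); na <- nrow(annotated)
  det_matched <- rep(FALSE, nd)
  ann_matched <- rep(FALSE, na)
  if (nd > 0L && na > 0L) {
    as_ <- annotated$start_s - tolerance_s
    ae_ <- annotated$end_s + tolerance_s
    for (i in seq_len(nd)) {
      hit <- detected$start_s[i] <= ae_ & detected$end_s[i] >= as_
      if (any(hit)) {
        det_matched[i] <- TRUE
        ann_matched[hit] <- TRUE
      }
    }
  }
  structure(list(tp = sum(ann_matched), fp = sum(!det_matched),
                 fn = sum(!ann_matched),
                 n_annotated = na, n_detected = nd),
            class = "event_counts")
}

#' @export
print.event_counts <- function(x, ...) {
  cat(sprintf("<event_counts> TP = %d, FP = %d, FN = %d (of %d annotated, %d detected)\n",
              x$tp, x$fp, x$fn, x$n_annotated, x$n_detected))
  invisible(x)
}

#' Event counts from explicit totals
#'
#' @param tp,fp,fn Non-negative integer counts.
#' @return An `event_counts` object.
#' @export
event_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn),
                 n_annotated = as.integer(tp + fn),
                 n_detected = NA_integer_),
            class = "event_counts")
}

#' Precision, recall and F1 of event detection
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and `f1` is
#' their harmonic mean. A zero denominator is an *undefined* metric — it
#' raises a classed error (`sowmotion_undefined_metric`) rather than
#' silently returning 0, so "no detections made" is distinguishable from
#' "all detections wrong". `f1(1, 0)` and other zero-sum inputs return 0
#' with a warning, the usual convention.
#'
#' @param counts An `event_counts` object.
#' @return A number in \[0, 1\].
#' @export
precision <- function(counts) {
  stopifnot(inherits(counts, "event_counts"))
  if (counts$tp + counts$fp == 0)
    stop_sowmotion("precision undefined: no detections (TP + FP = 0)",
                   "sowmotion_undefined_metric")
  counts$tp / (counts$tp + counts$fp)
}

#' @rdname precision
#' @export
recall <- function(counts) {
  stopifnot(inherits(counts, "event_counts"))
  if (counts$tp + counts$fn == 0)
    stop_sowmotion("recall undefined: no annotated events (TP + FN = 0)",
                   "sowmotion_undefined_metric")
  counts$tp / (counts$tp + counts$fn)
}

#' @rdname precision
#' @param precision,recall Numbers in \[0, 1\].
#' @export
f1 <- function(precision, recall) {
  if (precision + recall == 0) {
    warning("precision + recall = 0; returning F1 = 0", call. = FALSE)
    return(0)
  }
  2 * recall * precision / (recall + precision)
}

#' Frame-level confusion matrix and per-class F1
#'
#' Builds the confusion matrix (rows = true class, columns = predicted) over
#' the five posture classes and derives one-vs-rest F1 per class from its
#' margins (`F1_c = 2 TP_c / (2 TP_c + FP_c + FN_c)`), plus their unweighted
#' mean. Classes absent from both truth and predictions get `NA` and are
#' excluded from the mean.
#'
#' @param truth,predicted Equal-length vectors of labels (factors or
#'   characters over [posture_classes()], or any common label set).
#' @return An object of class `frame_confusion`: `confusion` (table),
#'   `per_class_f1`, `mean_f1`, `n`.
#' @export
frame_confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop_sowmotion("truth and predicted must have equal length",
                   "sowmotion_format_error")
  lev <- if (all(c(as.character(truth), as.character(predicted)) %in% .POSTURES))
    .POSTURES else sort(union(as.character(truth), as.character(predicted)))
  tab <- table(truth = factor(truth, levels = lev),
               predicted = factor(predicted, levels = lev))
  tp <- diag(tab)
  fp <- colSums(tab) - tp
  fn <- rowSums(tab) - tp
  denom <- 2 * tp + fp + fn
  f1s <- ifelse(denom == 0, NA_real_, 2 * tp / denom)
  names(f1s) <- lev
  structure(list(confusion = tab, per_class_f1 = f1s,
                 mean_f1 = mean(f1s, na.rm = TRUE),
                 n = length(truth)),
            class = "frame_confusion")
}

#' @export
print.frame_confusion <- function(x, ...) {
  print(x$confusion)
  cat("per-class F1:\n")
  print(round(x$per_class_f1, 3))
  cat(sprintf("mean F1: %.3f over %d frames\n", x$mean_f1, x$n))
  invisible(x)
}
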