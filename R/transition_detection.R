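## Threshold-based detection of posture-transition points on extended
## (12 s, 60 %-overlap) frames, and segmentation of each transition by an
## orientation-stabilization search on the 2-s frames.

#' Transition-detector configuration
#'
#' A pair of consecutive extended frames marks a candidate transition when
#' the absolute pitch change exceeds `theta_p` or the absolute roll change
#' exceeds `theta_r`. Candidates are confirmed only when at least
#' `confirm_adjacent` neighbouring frame pairs also satisfy the rule, which
#' rejects temporary position adjustments.
#'
#' Default thresholds: extended frames average orientation over 12 s with a
#' 4-s stride, which dilutes a step orientation change of `D` degrees to a
#' maximum consecutive-pair contrast of `D / 3`; with the adjacent-pair
#' confirmation the usable contrast for ramp-like transitions sits nearer
#' `D / 4`. The weakest orientation contrast among the posture classes is
#' the ~35° sitting pitch offset, so thresholds of 8° keep those transitions
#' detectable while remaining an order of magnitude above orientation noise.
#'
#' @param theta_p,theta_r Pitch and roll change thresholds, degrees.
#' @param group_size Number of consecutive base frames merged into one
#'   extended frame (6 x 2 s = 12 s by default).
#' @param overlap_fraction Fractional overlap of consecutive extended frames;
#'   realized as the nearest whole number of base frames
#'   (`stride = round(group_size * (1 - overlap_fraction))`).
#' @param confirm_adjacent Number of neighbouring pairs (searched up to this
#'   distance on either side) that must also satisfy the threshold rule.
#' @param stabilization_window_s Length of the consistent-orientation window
#'   the segmentation search looks for on each side of a transition point.
#' @param stability_tol_p,stability_tol_r Maximum pitch/roll variation
#'   (degrees) within a window still considered a consistent orientation;
#'   default one third of the detection thresholds.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(theta_p = 8, theta_r = 8, group_size = 6,
                             overlap_fraction = 0.6, confirm_adjacent = 1,
                             stabilization_window_s = 1.5,
                             stability_tol_p = theta_p / 3,
                             stability_tol_r = theta_r / 3) {
  if (!is_scalar_num(theta_p) || theta_p <= 0 ||
      !is_scalar_num(theta_r) || theta_r <= 0)
    stop_sowmotion("theta_p and theta_r must be positive",
                   "sowmotion_config_error")
  if (!is_count(group_size))
    stop_sowmotion("group_size must be a positive integer",
                   "sowmotion_config_error")
  if (!is_scalar_num(overlap_fraction) || overlap_fraction < 0 ||
      overlap_fraction >= 1)
    stop_sowmotion("overlap_fraction must lie in [0, 1)",
                   "sowmotion_config_error")
  if (!is_count(confirm_adjacent))
    stop_sowmotion("confirm_adjacent must be a positive integer",
                   "sowmotion_config_error")
  if (!is_scalar_num(stabilization_window_s) || stabilization_window_s <= 0)
    stop_sowmotion("stabilization_window_s must be positive",
                   "sowmotion_config_error")
  structure(list(theta_p = theta_p, theta_r = theta_r,
                 group_size = as.integer(group_size),
                 overlap_fraction = overlap_fraction,
                 confirm_adjacent = as.integer(confirm_adjacent),
                 stabilization_window_s = stabilization_window_s,
                 stability_tol_p = stability_tol_p,
                 stability_tol_r = stability_tol_r),
            class = "detection_config")
}

extended_stride <- function(cfg) {
  max(1L, as.integer(round(cfg$group_size * (1 - cfg$overlap_fraction))))
}

#' Combine base frames into overlapping extended frames
#'
#' Each extended frame spans `group_size` consecutive base frames; its pitch
#' and roll are recomputed from the mean gravity over the span and its
#' activity from the pooled raw-magnitude moments, so an extended frame is
#' exactly the feature triple that a single long frame over the same samples
#' would produce. Consecutive extended frames start `stride` base frames
#' apart (stride 2, i.e. 4 s, for the 12-s / 60 % defaults).
#'
#' @param frames A `feature_frames` data frame from [extract_features()].
#' @param cfg A [detection_config()].
#' @return A `feature_frames` data frame of extended frames.
#' @export
build_extended_frames <- function(frames, cfg = detection_config()) {
  nf <- nrow(frames)
  gs <- cfg$group_size
  if (nf < gs)
    stop_sowmotion("fewer frames than group_size", "sowmotion_empty_input")
  stride <- extended_stride(cfg)
  starts <- seq.int(1L, nf - gs + 1L, by = stride)
  span_mean <- function(v)
    vapply(starts, function(s) mean(v[s:(s + gs - 1L)]), numeric(1))
  gxm <- span_mean(frames$gx); gym <- span_mean(frames$gy)
  gzm <- span_mean(frames$gz)
  m1 <- span_mean(frames$m1); m2 <- span_mean(frames$m2)
  out <- data.frame(
    frame = seq_along(starts),
    start_s = frames$start_s[starts],
    end_s = frames$end_s[starts + gs - 1L],
    p = pitch(gxm, gym, gzm),
    r = roll(gxm, gym, gzm),
    a = sqrt(pmax(m2 - m1^2, 0)),
    gx = gxm, gy = gym, gz = gzm, m1 = m1, m2 = m2)
  structure(out, class = c("feature_frames", "data.frame"),
            rate_hz = attr(frames, "rate_hz"),
            frame_step_s = stride * frame_step_of(frames),
            animal_id = attr(frames, "animal_id"), extended = TRUE)
}

#' Detect posture-transition points from extended frames
#'
#' A pair of consecutive extended frames `(i - 1, i)` is a candidate when
#' `|p_i - p_{i-1}| > theta_p` or `|r_i - r_{i-1}| > theta_r`. A candidate is
#' confirmed when at least `confirm_adjacent` of the neighbouring pairs
#' (within `confirm_adjacent` pairs on either side) are also candidates.
#' Runs of consecutive confirmed pairs collapse to a single transition point:
#' the midpoint between (the centres of) the two frames in which the
#' threshold was first exceeded.
#'
#' @param ext Extended frames from [build_extended_frames()].
#' @param cfg A [detection_config()].
#' @return Numeric vector of transition-point times (seconds), possibly
#'   empty.
#' @export
detect_transition_points <- function(ext, cfg = detection_config()) {
  n <- nrow(ext)
  if (n < 2L)
    stop_sowmotion("need at least 2 extended frames",
                   "sowmotion_empty_input")
  cand <- abs(diff(ext$p)) > cfg$theta_p | abs(diff(ext$r)) > cfg$theta_r
  np <- length(cand)
  ca <- cfg$confirm_adjacent
  confirmed <- vapply(seq_len(np), function(j) {
    if (!cand[j]) return(FALSE)
    nb <- setdiff(seq.int(max(1L, j - ca), min(np, j + ca)), j)
    sum(cand[nb]) >= ca
  }, logical(1))
  if (!any(confirmed)) return(numeric(0))
  centres <- (ext$start_s + ext$end_s) / 2
  runs <- rle(confirmed)
  first_idx <- cumsum(c(1L, runs$lengths))[seq_along(runs$lengths)]
  firsts <- first_idx[runs$values]
  (centres[firsts] + centres[firsts + 1L]) / 2
}

consistent_window <- function(p, r, idx, tol_p, tol_r) {
  (max(p[idx]) - min(p[idx])) <= tol_p && (max(r[idx]) - min(r[idx])) <= tol_r
}

#' Segment one transition around a detected point
#'
#' Walks outward from the transition point over the base (2-s) frames and
#' places each boundary at the last time the orientation was consistent for
#' at least `stabilization_window_s` — i.e. a window of consecutive frames
#' whose pitch varies by no more than `stability_tol_p` and roll by no more
#' than `stability_tol_r`. The start boundary is the end of the nearest
#' consistent window wholly before the point; the end boundary is the start
#' of the nearest consistent window wholly after it. If no stabilization is
#' found before the trace edge the edge is used and the segment is flagged
#' `truncated`.
#'
#' @param frames Base `feature_frames` (2-s resolution).
#' @param point_s Transition-point time in seconds, within frame coverage.
#' @param cfg A [detection_config()].
#' @return One-row data frame with `start_s`, `point_s`, `end_s`,
#'   `truncated`.
#' @export
segment_transition <- function(frames, point_s, cfg = detection_config()) {
  nf <- nrow(frames)
  if (point_s < frames$start_s[1L] || point_s > frames$end_s[nf])
    stop_sowmotion("transition point outside frame coverage",
                   "sowmotion_interval_error")
  step <- frame_step_of(frames)
  k <- max(2L, as.integer(ceiling(cfg$stabilization_window_s / step)) + 1L)
  p <- frames$p; r <- frames$r
  tol_p <- cfg$stability_tol_p; tol_r <- cfg$stability_tol_r

  truncated <- FALSE
  ## leftward: windows [j - k + 1, j] ending strictly before the point
  j <- max(which(frames$end_s < point_s), 0L)
  start_s <- frames$start_s[1L]
  found <- FALSE
  while (j - k + 1L >= 1L) {
    if (consistent_window(p, r, (j - k + 1L):j, tol_p, tol_r)) {
      start_s <- frames$end_s[j]
      found <- TRUE
      break
    }
    j <- j - 1L
  }
  if (!found) truncated <- TRUE
  ## rightward: windows [j, j + k - 1] starting strictly after the point
  jr <- suppressWarnings(min(which(frames$start_s > point_s)))
  end_s <- frames$end_s[nf]
  found_r <- FALSE
  if (is.finite(jr)) {
    while (jr + k - 1L <= nf) {
      if (consistent_window(p, r, jr:(jr + k - 1L), tol_p, tol_r)) {
        end_s <- frames$start_s[jr]
        found_r <- TRUE
        break
      }
      jr <- jr + 1L
    }
  }
  if (!found_r) truncated <- TRUE
  if (end_s <= start_s) {  # degenerate stabilization straddle; widen minimally
    start_s <- max(frames$start_s[1L], point_s - step)
    end_s <- min(frames$end_s[nf], point_s + step)
  }
  data.frame(start_s = start_s, point_s = point_s, end_s = end_s,
             truncated = truncated)
}

#' Detect and segment all posture transitions in a trace
#'
#' Full detection pipeline: feature extraction, extended-frame construction,
#' threshold detection and stabilization segmentation. Segments from nearby
#' points that overlap in time are merged (the first point is kept), so the
#' result is a time-ordered, non-overlapping set of transitions.
#'
#' @param trace A [signal_trace()].
#' @param fcfg A [filter_config()].
#' @param wcfg A [frame_config()].
#' @param dcfg A [detection_config()].
#' @return Data frame of class `transition_segments` with columns
#'   `animal_id`, `start_s`, `point_s`, `end_s`, `truncated`.
#' @export
detect_and_segment <- function(trace, fcfg = filter_config(),
                               wcfg = frame_config(),
                               dcfg = detection_config()) {
  frames <- extract_features(trace, fcfg, wcfg)
  empty <- data.frame(animal_id = character(), start_s = numeric(),
                      point_s = numeric(), end_s = numeric(),
                      truncated = logical())
  if (nrow(frames) < dcfg$group_size + 1L)
    return(structure(empty, class = c("transition_segments", "data.frame")))
  ext <- build_extended_frames(frames, dcfg)
  if (nrow(ext) < 2L)
    return(structure(empty, class = c("transition_segments", "data.frame")))
  pts <- detect_transition_points(ext, dcfg)
  if (length(pts) == 0L)
    return(structure(empty, class = c("transition_segments", "data.frame")))
  segs <- do.call(rbind, lapply(pts, segment_transition,
                                frames = frames, cfg = dcfg))
  segs <- segs[order(segs$start_s, segs$point_s), , drop = FALSE]
  ## merge overlapping segments
  merged <- segs[1L, , drop = FALSE]
  if (nrow(segs) > 1L) {
    for (i in 2:nrow(segs)) {
      last <- nrow(merged)
      if (segs$start_s[i] <= merged$end_s[last]) {
        merged$end_s[last] <- max(merged$end_s[last], segs$end_s[i])
        merged$truncated[last] <- merged$truncated[last] || segs$truncated[i]
      } else {
        merged <- rbind(merged, segs[i, , drop = FALSE])
      }
    }
  }
  merged <- cbind(animal_id = trace$animal_id, merged)
  rownames(merged) <- NULL
  structure(merged, class = c("transition_segments", "data.frame"),
            rate_hz = trace$rate_hz)
}
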