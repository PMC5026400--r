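## Kinematic descriptors of each segmented transition: duration, peak
## acceleration, per-axis acceleration range, jerk, and pitch/roll rates.
## The first four are computed from raw samples; the orientation rates from
## the preprocessed (feature-frame) values.

trace_window <- function(trace, start_s, end_s) {
  r <- trace$rate_hz
  i0 <- max(1L, as.integer(floor(start_s * r)) + 1L)
  i1 <- min(n_samples(trace), as.integer(ceiling(end_s * r)))
  if (i1 < i0)
    stop_sowmotion("empty trace window", "sowmotion_empty_input")
  i0:i1
}

#' Duration of a transition
#' @param seg A one-row transition segment (columns `start_s`, `end_s`).
#' @return Duration in seconds.
#' @export
transition_duration <- function(seg) seg$end_s - seg$start_s

#' Peak acceleration within a window
#'
#' Maximum of the per-sample magnitude over the raw samples of the window —
#' with all axes considered together a motionless sensor reads about 1 g0
#' and an abrupt "flop" impact spikes well above it.
#'
#' @param trace A [signal_trace()].
#' @param start_s,end_s Window bounds in seconds.
#' @return Peak magnitude in g0.
#' @export
peak_acceleration <- function(trace, start_s, end_s) {
  idx <- trace_window(trace, start_s, end_s)
  max(magnitude(trace$x[idx], trace$y[idx], trace$z[idx]))
}

#' Acceleration range within a window
#'
#' Per-axis `max - min` over the raw samples; the largest of the three axis
#' ranges is returned, representing the largest change in acceleration in
#' any one direction.
#'
#' @inheritParams peak_acceleration
#' @return Range in g0.
#' @export
acceleration_range <- function(trace, start_s, end_s) {
  idx <- trace_window(trace, start_s, end_s)
  if (length(idx) < 2L)
    stop_sowmotion("acceleration range needs at least 2 samples",
                   "sowmotion_empty_input")
  max(diff(range(trace$x[idx])), diff(range(trace$y[idx])),
      diff(range(trace$z[idx])))
}

#' Jerk within a window
#'
#' Jerk is the first time-derivative of acceleration. It is computed as the
#' discrete first difference of the magnitude series scaled by the sampling
#' rate, and summarised as the maximum absolute value over the window — a
#' hind-end coming to a sudden stop produces a large value, the same
#' deceleration spread over a longer time a small one.
#'
#' @inheritParams peak_acceleration
#' @return Maximum absolute jerk in g0 per second.
#' @export
jerk <- function(trace, start_s, end_s) {
  idx <- trace_window(trace, start_s, end_s)
  if (length(idx) < 2L)
    stop_sowmotion("jerk needs at least 2 samples", "sowmotion_empty_input")
  m <- magnitude(trace$x[idx], trace$y[idx], trace$z[idx])
  max(abs(diff(m))) * trace$rate_hz
}

#' Pitch and roll rates within a segment
#'
#' Maximum absolute frame-to-frame change of pitch (and of roll) divided by
#' the frame step, over the feature frames inside the segment. These are the
#' smoothness descriptors: unlike jerk they are computed from the
#' preprocessed per-frame orientation, not the raw samples. If fewer than
#' two frame midpoints fall inside the segment, the two frames nearest the
#' segment centre are used.
#'
#' @param frames A `feature_frames` data frame.
#' @param start_s,end_s Segment bounds in seconds.
#' @return Named numeric vector `c(pitch_rate, roll_rate)`, degrees/second.
#' @export
orientation_rates <- function(frames, start_s, end_s) {
  if (nrow(frames) < 2L)
    stop_sowmotion("orientation rates need at least 2 frames",
                   "sowmotion_empty_input")
  mid <- (frames$start_s + frames$end_s) / 2
  sel <- which(mid >= start_s & mid <= end_s)
  if (length(sel) < 2L) {
    ctr <- (start_s + end_s) / 2
    sel <- order(abs(mid - ctr))[1:2]
    sel <- sort(sel)
  }
  step <- frame_step_of(frames)
  c(pitch_rate = max(abs(diff(frames$p[sel]))) / step,
    roll_rate = max(abs(diff(frames$r[sel]))) / step)
}

#' Kinematic features of detected transitions
#'
#' Computes the six descriptors for each segment: `duration_s`,
#' `peak_accel`, `accel_range` and `jerk` from the raw samples of
#' `[start_s, end_s]`, and `pitch_rate` / `roll_rate` from the feature
#' frames.
#'
#' @param segments A `transition_segments` data frame (or any data frame
#'   with `start_s`, `end_s`).
#' @param trace The [signal_trace()] the segments were detected in.
#' @param frames Base `feature_frames` of the same trace; computed on the
#'   fly if omitted.
#' @param fcfg,wcfg Configurations used when `frames` is omitted.
#' @return Data frame of class `transition_features` with one row per
#'   segment and the six feature columns.
#' @export
transition_features <- function(segments, trace, frames = NULL,
                                fcfg = filter_config(),
                                wcfg = frame_config()) {
  if (is.null(frames)) frames <- extract_features(trace, fcfg, wcfg)
  n <- nrow(segments)
  out <- data.frame(start_s = numeric(n), end_s = numeric(n),
                    duration_s = numeric(n), peak_accel = numeric(n),
                    accel_range = numeric(n), jerk = numeric(n),
                    pitch_rate = numeric(n), roll_rate = numeric(n))
  for (i in seq_len(n)) {
    s <- segments$start_s[i]; e <- segments$end_s[i]
    rates <- orientation_rates(frames, s, e)
    out[i, ] <- c(s, e, e - s,
                  peak_acceleration(trace, s, e),
                  acceleration_range(trace, s, e),
                  jerk(trace, s, e),
                  rates[["pitch_rate"]], rates[["roll_rate"]])
  }
  if (n > 0L && "animal_id" %in% names(segments))
    out <- cbind(animal_id = segments$animal_id, out)
  structure(out, class = c("transition_features", "data.frame"))
}
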