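## Static-acceleration (gravity) estimation and the per-frame feature triple
## {pitch p, roll r, activity a}.

#' Gravity filter configuration
#'
#' The static (gravity) component of the signal is estimated per axis with
#' the recursive exponential filter
#' `g_i(t) = alpha * s_i(t) + (1 - alpha) * g_i(t - 1)`.
#' `alpha` trades responsiveness against noise suppression; the default 0.01
#' at 100 Hz gives a time constant of about 1 s, fast enough to track posture
#' changes (several seconds) while suppressing gait and sensor noise.
#'
#' @param alpha Filter weight in (0, 1]. `alpha = 1` returns the raw signal.
#' @param initial_state `"first_sample"` seeds the filter with the first
#'   sample (so a constant input is a fixed point from the start) or
#'   `"zero"`.
#' @param literal_sign If `TRUE`, uses the recursion
#'   `g = alpha * s - (1 - alpha) * g_prev` instead. That form does not
#'   converge to the input mean and is provided for auditing only; the
#'   default smoothing form is used everywhere else in the package.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(alpha = 0.01,
                          initial_state = c("first_sample", "zero"),
                          literal_sign = FALSE) {
  if (!is_scalar_num(alpha) || alpha <= 0 || alpha > 1)
    stop_sowmotion("alpha must lie in (0, 1]", "sowmotion_config_error")
  initial_state <- match.arg(initial_state)
  structure(list(alpha = alpha, initial_state = initial_state,
                 literal_sign = isTRUE(literal_sign)),
            class = "filter_config")
}

#' Framing configuration
#'
#' Features are computed over consecutive non-overlapping frames of
#' `frame_seconds` seconds (200 samples at 100 Hz for the default 2 s).
#'
#' @param frame_seconds Frame length in seconds.
#' @return An object of class `frame_config`.
#' @export
frame_config <- function(frame_seconds = 2) {
  if (!is_scalar_num(frame_seconds) || frame_seconds <= 0)
    stop_sowmotion("frame_seconds must be positive", "sowmotion_config_error")
  structure(list(frame_seconds = frame_seconds), class = "frame_config")
}

#' Estimate the static (gravity) acceleration of a trace
#'
#' Applies the recursive exponential filter of [filter_config()] to each
#' axis. The output has the same length and rate as the input; for bounded
#' input the estimate stays within the input bounds (each output sample is a
#' convex combination of input samples).
#'
#' @param trace A [signal_trace()].
#' @param cfg A [filter_config()].
#' @return A `signal_trace` (additional class `gravity_trace`) holding the
#'   per-sample gravity estimate.
#' @export
estimate_static_acceleration <- function(trace, cfg = filter_config()) {
  stopifnot(inherits(trace, "signal_trace"), inherits(cfg, "filter_config"))
  if (n_samples(trace) < 1L)
    stop_sowmotion("empty trace", "sowmotion_empty_input")
  a <- cfg$alpha
  coef <- if (cfg$literal_sign) -(1 - a) else (1 - a)
  smooth_axis <- function(s) {
    init <- if (cfg$initial_state == "first_sample") s[1L] else 0
    as.double(stats::filter(a * s, coef, method = "recursive", init = init))
  }
  g <- trace
  g$x <- smooth_axis(trace$x)
  g$y <- smooth_axis(trace$y)
  g$z <- smooth_axis(trace$z)
  class(g) <- c("gravity_trace", "signal_trace")
  g
}

axes3 <- function(gx, gy, gz) {
  ## accept a length-3 vector, an n x 3 matrix, or three vectors
  if (is.null(gy) && is.null(gz)) {
    if (is.matrix(gx)) {
      stopifnot(ncol(gx) == 3L)
      return(list(x = gx[, 1L], y = gx[, 2L], z = gx[, 3L]))
    }
    stopifnot(length(gx) == 3L)
    return(list(x = gx[1L], y = gx[2L], z = gx[3L]))
  }
  stopifnot(length(gx) == length(gy), length(gy) == length(gz))
  list(x = gx, y = gy, z = gz)
}

#' Pitch angle of a gravity vector
#'
#' `pitch(g) = atan(gy / sqrt(gx^2 + gz^2))` in degrees, in `[-90, 90]`.
#' Pitch is the rotation of the hind-end sensor toward/away from vertical and
#' changes when the sow lowers her hind-end to sit or lie. The boundary
#' values ±90 are returned when `gx = gz = 0`; the all-zero vector has no
#' orientation and raises an error.
#'
#' @param gx,gy,gz Gravity components in g0: either three numeric vectors,
#'   a single length-3 vector, or an `n x 3` matrix passed as `gx`.
#' @return Pitch in degrees.
#' @export
pitch <- function(gx, gy = NULL, gz = NULL) {
  g <- axes3(gx, gy, gz)
  h <- sqrt(g$x^2 + g$z^2)
  if (any(h == 0 & g$y == 0))
    stop_sowmotion("zero gravity vector has undefined orientation",
                   "sowmotion_orientation_error")
  atan2(g$y, h) * 180 / pi
}

#' Roll angle of a gravity vector
#'
#' Quadrant-aware `roll(g) = atan2(-gx, gz)` in degrees, in `(-180, 180]`.
#' Roll is the rotation about the animal's long (craniocaudal) axis and
#' distinguishes left from right lateral lying. The two-argument arctangent
#' is required to reach the full range; `gx = gz = 0` (sensor pointing
#' straight along the mediolateral axis) has undefined roll and raises an
#' error.
#'
#' @inheritParams pitch
#' @return Roll in degrees.
#' @export
roll <- function(gx, gy = NULL, gz = NULL) {
  g <- axes3(gx, gy, gz)
  if (any(g$x == 0 & g$z == 0))
    stop_sowmotion("roll undefined when gx = gz = 0",
                   "sowmotion_orientation_error")
  ## 0 - gx (not -gx) so a zero gx stays +0 and atan2(+0, -1) = +180,
  ## keeping the boundary on the +180 side of the (-180, 180] range
  atan2(0 - g$x, g$z) * 180 / pi
}

#' Euclidean magnitude of acceleration samples
#'
#' @inheritParams pitch
#' @return `sqrt(x^2 + y^2 + z^2)` per sample, in g0.
#' @export
magnitude <- function(gx, gy = NULL, gz = NULL) {
  g <- axes3(gx, gy, gz)
  sqrt(g$x^2 + g$y^2 + g$z^2)
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Activity level of a frame of samples
#'
#' The population standard deviation of the per-sample magnitude series
#' within the frame — a movement-intensity proxy that is invariant to sensor
#' orientation.
#'
#' @inheritParams pitch
#' @return Activity in g0 (non-negative).
#' @export
activity <- function(gx, gy = NULL, gz = NULL) {
  m <- magnitude(gx, gy, gz)
  if (length(m) < 2L)
    stop_sowmotion("activity needs at least 2 samples",
                   "sowmotion_empty_input")
  pop_sd(m)
}

#' Extract per-frame posture features from a trace
#'
#' Divides the trace into consecutive non-overlapping frames of
#' `wcfg$frame_seconds` (trailing partial frame dropped) and computes, per
#' frame, the feature triple:
#' * `p` — pitch of the frame-mean gravity estimate (degrees),
#' * `r` — roll of the frame-mean gravity estimate (degrees),
#' * `a` — activity, the population SD of the raw magnitude series (g0).
#'
#' Orientation is computed from the frame mean of the per-sample gravity
#' estimate (averaging the vector, then taking angles) which avoids
#' angle-wrapping artifacts near the roll boundary. The returned frame also
#' carries the mean gravity components and the first two raw-magnitude
#' moments, which allow extended frames to be aggregated exactly.
#'
#' @param trace A [signal_trace()].
#' @param fcfg A [filter_config()].
#' @param wcfg A [frame_config()].
#' @return A data frame of class `feature_frames` with columns `frame`,
#'   `start_s`, `end_s`, `p`, `r`, `a` (plus aggregation columns `gx`, `gy`,
#'   `gz`, `m1`, `m2`), and attributes `rate_hz`, `frame_step_s`,
#'   `animal_id`.
#' @export
extract_features <- function(trace, fcfg = filter_config(),
                             wcfg = frame_config()) {
  stopifnot(inherits(trace, "signal_trace"), inherits(wcfg, "frame_config"))
  fs <- as.integer(round(wcfg$frame_seconds * trace$rate_hz))
  if (fs < 2L)
    stop_sowmotion("frame must cover at least 2 samples",
                   "sowmotion_config_error")
  nf <- n_samples(trace) %/% fs
  if (nf < 1L)
    stop_sowmotion("trace shorter than one frame", "sowmotion_empty_input")
  used <- seq_len(nf * fs)
  g <- estimate_static_acceleration(trace, fcfg)
  fmean <- function(v) .colMeans(v[used], fs, nf)
  gxm <- fmean(g$x); gym <- fmean(g$y); gzm <- fmean(g$z)
  m <- magnitude(trace$x[used], trace$y[used], trace$z[used])
  m1 <- .colMeans(m, fs, nf)
  m2 <- .colMeans(m^2, fs, nf)
  step <- fs / trace$rate_hz
  out <- data.frame(
    frame = seq_len(nf),
    start_s = (seq_len(nf) - 1) * step,
    end_s = seq_len(nf) * step,
    p = pitch(gxm, gym, gzm),
    r = roll(gxm, gym, gzm),
    a = sqrt(pmax(m2 - m1^2, 0)),
    gx = gxm, gy = gym, gz = gzm, m1 = m1, m2 = m2)
  structure(out, class = c("feature_frames", "data.frame"),
            rate_hz = trace$rate_hz, frame_step_s = step,
            frame_seconds = wcfg$frame_seconds, animal_id = trace$animal_id)
}

frame_step_of <- function(frames) {
  st <- attr(frames, "frame_step_s")
  if (!is.null(st)) return(st)
  if (nrow(frames) >= 2L) return(frames$start_s[2L] - frames$start_s[1L])
  frames$end_s[1L] - frames$start_s[1L]
}
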