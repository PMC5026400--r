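## Semi-Markov sow-motion simulator: draws a posture/transition schedule,
## synthesises the tri-axial acceleration signal it implies, and returns the
## trace together with ground-truth annotations and per-transition
## parameters, so every pipeline stage can be tested without animal data.

default_orientations <- function() {
  ## (pitch, roll) targets per posture, degrees. Standing and sternal lying
  ## share the upright orientation and are separated by activity only;
  ## sitting lowers the hind-end (pitch offset); lateral lies roll to ±90.
  rbind(ST = c(0, 0), S = c(-35, 0), LL = c(0, -90), RL = c(0, 90),
        SL = c(0, 0))
}

default_orientation_jitter <- function() {
  ## per-dwell orientation variability (sd of pitch, roll offsets, degrees):
  ## a sow never reoccupies exactly the same position; sitting is the most
  ## variable posture, which is what makes it hard to classify.
  rbind(ST = c(5, 5), S = c(14, 8), LL = c(5, 8), RL = c(5, 8), SL = c(6, 6))
}

default_dwell_means <- function() {
  ## mean dwell per posture visit (s); lateral lying dominates the budget,
  ## sitting is brief and rare
  c(ST = 240, S = 60, LL = 1500, RL = 1500, SL = 700)
}

default_activity_sd <- function() {
  ## within-posture movement jitter (g0): standing/nest-building is the
  ## high-activity regime, lateral lying the quietest
  c(ST = 0.08, S = 0.04, LL = 0.008, RL = 0.008, SL = 0.015)
}

default_transition_pref <- function() {
  ## next-posture preference weights (row = from). Stand<->lie moves are the
  ## preferred transitions. Direct ST<->SL swaps are excluded: both postures
  ## share the upright sensor orientation, and a real crated sow descends
  ## from standing to sternal lying through a kneel/sit phase, so the
  ## simulator routes those moves through S.
  m <- rbind(ST = c(0, 0.5, 2.5, 2.5, 0),
             S  = c(0.5, 0, 2, 2, 0.5),
             LL = c(2, 0.5, 0, 1, 1.5),
             RL = c(2, 0.5, 1, 0, 1.5),
             SL = c(0, 1, 1.5, 1.5, 0))
  colnames(m) <- rownames(m)
  m
}

#' Simulator configuration
#'
#' Parameters of the semi-Markov sow-motion simulator. A simulated recording
#' alternates posture dwells (shifted-exponential lengths, mean
#' `dwell_mean_s` per posture, minimum `min_dwell_s` — a posture held
#' shorter than that would be annotated as part of the transition) with
#' transitions of uniformly drawn duration, during which the sensor
#' orientation moves between the bounding dwells' orientations along a
#' sigmoid, an impact spike proportional to the drawn abruptness lands on
#' the magnitude (the "flopping" signature) and movement jitter is raised.
#' White sensor noise of `noise_sd` is added throughout. An optional
#' pre-farrowing surge multiplies the transition rate (divides dwell means)
#' inside a window, emulating nest building.
#'
#' @param duration_h Recording length in hours.
#' @param rate_hz Sampling rate (nominally 100).
#' @param seed Default seed used by [simulate_sow()] when none is given.
#' @param animal_id Identifier stamped on the outputs.
#' @param posture_orientations 5x2 matrix of (pitch, roll) targets, degrees,
#'   rows named by [posture_classes()].
#' @param orientation_jitter_sd 5x2 matrix of per-dwell orientation offset
#'   SDs, degrees.
#' @param dwell_mean_s Named mean dwell lengths per posture, seconds.
#' @param min_dwell_s Minimum dwell length, seconds.
#' @param transition_duration_range_s Range the transition durations are
#'   drawn from, seconds.
#' @param abruptness_range Range of the impact-spike amplitude (g0); the
#'   peak signal magnitude of a transition is about `1 + abruptness`.
#' @param sigmoid_steepness Steepness of the orientation sigmoid (the
#'   central ~27 % of the nominal duration carries 90 % of the change at the
#'   default 16, leaving the stabilization plateaus the segmentation search
#'   needs).
#' @param spike_duration_s Length of the half-sine impact spike, seconds.
#' @param noise_sd White sensor-noise SD per axis, g0.
#' @param activity_sd Named per-posture movement-jitter SDs, g0.
#' @param activity_lognorm_sd Log-scale SD of the per-dwell activity
#'   multiplier (makes activity levels overlap between postures).
#' @param transition_activity_sd Movement jitter during transitions, g0.
#' @param jitter_ar AR(1) coefficient of the movement jitter (band-limits
#'   body movement to a few Hz at 100 Hz sampling; sensor noise stays
#'   white).
#' @param transition_pref 5x5 next-posture preference weight matrix
#'   (diagonal ignored).
#' @param farrowing_surge `NULL` or `list(start_h, end_h, rate_multiplier)`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration_h = 24, rate_hz = 100, seed = 1,
                       animal_id = "sim",
                       posture_orientations = default_orientations(),
                       orientation_jitter_sd = default_orientation_jitter(),
                       dwell_mean_s = default_dwell_means(),
                       min_dwell_s = 20,
                       transition_duration_range_s = c(8, 16),
                       abruptness_range = c(0.2, 3),
                       sigmoid_steepness = 16,
                       spike_duration_s = 0.3,
                       noise_sd = 0.01,
                       activity_sd = default_activity_sd(),
                       activity_lognorm_sd = 0.4,
                       transition_activity_sd = 0.05,
                       jitter_ar = 0.9,
                       transition_pref = default_transition_pref(),
                       farrowing_surge = NULL) {
  if (!is_scalar_num(duration_h) || duration_h <= 0)
    stop_sowmotion("duration_h must be positive", "sowmotion_config_error")
  if (!is_scalar_num(noise_sd) || noise_sd < 0)
    stop_sowmotion("noise_sd must be non-negative", "sowmotion_config_error")
  stopifnot(all(.POSTURES %in% rownames(posture_orientations)),
            all(.POSTURES %in% names(dwell_mean_s)),
            all(.POSTURES %in% names(activity_sd)),
            length(transition_duration_range_s) == 2L,
            length(abruptness_range) == 2L)
  if (any(dwell_mean_s <= max(transition_duration_range_s)))
    stop_sowmotion("dwell means must exceed the transition durations",
                   "sowmotion_config_error")
  if (!is.null(farrowing_surge))
    stopifnot(all(c("start_h", "end_h", "rate_multiplier") %in%
                    names(farrowing_surge)))
  structure(list(
    duration_h = duration_h, rate_hz = rate_hz, seed = seed,
    animal_id = animal_id,
    posture_orientations = posture_orientations[.POSTURES, , drop = FALSE],
    orientation_jitter_sd = orientation_jitter_sd[.POSTURES, , drop = FALSE],
    dwell_mean_s = dwell_mean_s[.POSTURES], min_dwell_s = min_dwell_s,
    transition_duration_range_s = as.numeric(transition_duration_range_s),
    abruptness_range = as.numeric(abruptness_range),
    sigmoid_steepness = sigmoid_steepness,
    spike_duration_s = spike_duration_s,
    noise_sd = noise_sd, activity_sd = activity_sd[.POSTURES],
    activity_lognorm_sd = activity_lognorm_sd,
    transition_activity_sd = transition_activity_sd,
    jitter_ar = jitter_ar,
    transition_pref = transition_pref[.POSTURES, .POSTURES],
    farrowing_surge = farrowing_surge), class = "sim_config")
}

#' Build a unit gravity vector from pitch and roll
#'
#' Inverse of the orientation equations: for pitch `p` in (-90, 90) and roll
#' `r` in (-180, 180], returns the unit vector `g` with `pitch(g) = p` and
#' `roll(g) = r` (to numerical precision). Used to construct synthetic
#' signals from target orientations.
#'
#' @param pitch_deg,roll_deg Orientation angles in degrees (vectorized).
#' @return An `n x 3` matrix of unit gravity vectors (columns x, y, z).
#' @export
invert_orientation <- function(pitch_deg, roll_deg) {
  if (any(pitch_deg <= -90 | pitch_deg >= 90))
    stop_sowmotion("pitch must lie strictly inside (-90, 90)",
                   "sowmotion_orientation_error")
  if (any(roll_deg <= -180 | roll_deg > 180))
    stop_sowmotion("roll must lie in (-180, 180]",
                   "sowmotion_orientation_error")
  p <- pitch_deg * pi / 180
  r <- roll_deg * pi / 180
  h <- cos(p)
  cbind(x = -h * sin(r), y = sin(p), z = h * cos(r))
}

surge_multiplier <- function(cfg, t_s) {
  fs <- cfg$farrowing_surge
  if (is.null(fs)) return(1)
  if (t_s >= fs$start_h * 3600 && t_s < fs$end_h * 3600) fs$rate_multiplier
  else 1
}

#' Draw a posture/transition schedule
#'
#' The semi-Markov skeleton of a simulation: alternating posture dwells and
#' transitions that tile `[0, duration]` exactly. Exposed separately so
#' behaviour-level summaries (transition frequency, surge shape) can be
#' studied at long horizons without synthesising the signal.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return List with data frames `postures` (`start_s`, `end_s`, `label`,
#'   `pitch`, `roll`, `act_sd`) and `transitions` (`start_s`, `end_s`,
#'   `from`, `to`, `duration_s`, `abruptness`).
#' @export
simulate_schedule <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  total <- cfg$duration_h * 3600
  ors <- cfg$posture_orientations
  jit <- cfg$orientation_jitter_sd

  draw_dwell <- function(posture, at) {
    mult <- surge_multiplier(cfg, at)
    m <- max(cfg$dwell_mean_s[[posture]] / mult, cfg$min_dwell_s + 1)
    cfg$min_dwell_s + stats::rexp(1L, rate = 1 / (m - cfg$min_dwell_s))
  }
  draw_state <- function(posture) {
    list(posture = posture,
         pitch = ors[posture, 1L] + stats::rnorm(1L, 0, jit[posture, 1L]),
         roll = ors[posture, 2L] + stats::rnorm(1L, 0, jit[posture, 2L]),
         act = cfg$activity_sd[[posture]] *
           exp(stats::rnorm(1L, 0, cfg$activity_lognorm_sd)))
  }

  start_p <- sample(c("ST", "LL", "RL", "SL"), 1L)
  state <- draw_state(start_p)
  t <- 0
  pos <- list(); tra <- list()
  while (t < total) {
    dwell <- draw_dwell(state$posture, t)
    p_end <- min(t + dwell, total)
    pos[[length(pos) + 1L]] <- data.frame(
      start_s = t, end_s = p_end, label = state$posture,
      pitch = state$pitch, roll = state$roll, act_sd = state$act)
    t <- p_end
    if (t >= total) break
    dur <- stats::runif(1L, cfg$transition_duration_range_s[1L],
                        cfg$transition_duration_range_s[2L])
    if (t + dur >= total) {
      ## a cut transition is meaningless; extend the last dwell to the end
      pos[[length(pos)]]$end_s <- total
      t <- total
      break
    }
    w <- cfg$transition_pref[state$posture, ]
    w[state$posture] <- 0
    nxt <- sample(.POSTURES, 1L, prob = w)
    new_state <- draw_state(nxt)
    tra[[length(tra) + 1L]] <- data.frame(
      start_s = t, end_s = t + dur, from = state$posture, to = nxt,
      duration_s = dur,
      abruptness = stats::runif(1L, cfg$abruptness_range[1L],
                                cfg$abruptness_range[2L]))
    t <- t + dur
    state <- new_state
  }
  postures <- do.call(rbind, pos)
  transitions <- if (length(tra) > 0L) do.call(rbind, tra) else
    data.frame(start_s = numeric(), end_s = numeric(), from = character(),
               to = character(), duration_s = numeric(),
               abruptness = numeric())
  list(postures = postures, transitions = transitions)
}

## normalized sigmoid on [0, 1]: exactly 0 at u = 0 and 1 at u = 1
unit_sigmoid <- function(u, k) {
  lo <- stats::plogis(-k / 2)
  hi <- stats::plogis(k / 2)
  (stats::plogis(k * (u - 0.5)) - lo) / (hi - lo)
}

#' Simulate one sow's accelerometer recording
#'
#' Draws a schedule with [simulate_schedule()] and synthesises the implied
#' tri-axial signal at `cfg$rate_hz`: per-sample orientation (constant
#' within dwells, sigmoid during transitions) converted to a unit gravity
#' vector, an impact spike along the gravity direction at 60 % of each
#' transition whose amplitude is the drawn abruptness, per-posture movement
#' jitter, and white sensor noise. Fully reproducible from the seed.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#' @return An object of class `sow_simulation`: `trace` ([signal_trace()]),
#'   `truth` ([annotation_track()]), `transition_params` (per-transition
#'   ground truth) and `schedule`.
#' @export
simulate_sow <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  sched <- simulate_schedule(cfg, seed = seed)
  ## continue from the schedule's RNG state so signal noise is seed-coupled
  rate <- cfg$rate_hz
  n <- as.integer(round(cfg$duration_h * 3600 * rate))
  tt <- (seq_len(n) - 1) / rate

  pitch_arr <- numeric(n)
  roll_arr <- numeric(n)
  act_arr <- numeric(n)
  pos <- sched$postures
  tra <- sched$transitions
  idx_of <- function(s, e) {
    i0 <- as.integer(floor(s * rate)) + 1L
    i1 <- min(n, as.integer(ceiling(e * rate)))
    if (i1 < i0) integer(0) else i0:i1
  }
  for (i in seq_len(nrow(pos))) {
    idx <- idx_of(pos$start_s[i], pos$end_s[i])
    pitch_arr[idx] <- pos$pitch[i]
    roll_arr[idx] <- pos$roll[i]
    act_arr[idx] <- pos$act_sd[i]
  }
  if (nrow(tra) > 0L) {
    for (i in seq_len(nrow(tra))) {
      idx <- idx_of(tra$start_s[i], tra$end_s[i])
      if (length(idx) == 0L) next
      u <- (tt[idx] - tra$start_s[i]) / tra$duration_s[i]
      sgm <- unit_sigmoid(pmin(pmax(u, 0), 1), cfg$sigmoid_steepness)
      p0 <- pos$pitch[i]; p1 <- pos$pitch[i + 1L]
      r0 <- pos$roll[i]; r1 <- pos$roll[i + 1L]
      pitch_arr[idx] <- p0 + (p1 - p0) * sgm
      ## roll is interpolated directly (no wrapping): the posture geometry
      ## keeps roll well inside (-180, 180), and the direct path between
      ## lateral lies passes through sternal, as a real sow rolls
      roll_arr[idx] <- r0 + (r1 - r0) * sgm
      act_arr[idx] <- cfg$transition_activity_sd
    }
  }
  g <- invert_orientation(pmin(pmax(pitch_arr, -89.9), 89.9), roll_arr)

  ## impact spikes along the instantaneous gravity direction
  if (nrow(tra) > 0L) {
    d <- cfg$spike_duration_s
    for (i in seq_len(nrow(tra))) {
      ctr <- tra$start_s[i] + 0.6 * tra$duration_s[i]
      idx <- idx_of(ctr - d / 2, ctr + d / 2)
      if (length(idx) == 0L) next
      amp <- tra$abruptness[i] * sin(pi * (tt[idx] - (ctr - d / 2)) / d)
      amp <- pmax(amp, 0)
      g[idx, ] <- g[idx, ] + g[idx, ] * amp
    }
  }

  ## movement jitter is band-limited (a body does not shake at the Nyquist
  ## rate): AR(1) process with marginal sd act_arr; sensor noise stays white
  rho <- cfg$jitter_ar
  move_axis <- function() {
    e <- stats::rnorm(n) * sqrt(1 - rho^2)
    as.double(stats::filter(e, rho, method = "recursive")) * act_arr
  }
  x <- g[, 1L] + move_axis() + stats::rnorm(n) * cfg$noise_sd
  y <- g[, 2L] + move_axis() + stats::rnorm(n) * cfg$noise_sd
  z <- g[, 3L] + move_axis() + stats::rnorm(n) * cfg$noise_sd

  trace <- signal_trace(x, y, z, rate_hz = rate, animal_id = cfg$animal_id)
  truth <- annotation_track(
    cfg$animal_id,
    pos[, c("start_s", "end_s", "label")],
    tra[, c("start_s", "end_s"), drop = FALSE])
  params <- tra
  structure(list(trace = trace, truth = truth, transition_params = params,
                 schedule = sched, config = cfg, seed = seed),
            class = "sow_simulation")
}

#' @export
print.sow_simulation <- function(x, ...) {
  cat(sprintf("<sow_simulation> %s: %.1f h at %g Hz, %d transitions (seed %d)\n",
              x$config$animal_id, x$config$duration_h, x$config$rate_hz,
              nrow(x$transition_params), x$seed))
  invisible(x)
}

#' Simulate a cohort of sows
#'
#' Runs [simulate_sow()] once per animal with per-animal seeds derived as
#' `seed * 1000 + index` and animal ids `sow1, sow2, ...`.
#'
#' @param n_animals Number of animals.
#' @param cfg A [sim_config()] shared by the cohort.
#' @param seed Base seed.
#' @return Named list of `sow_simulation` objects.
#' @export
simulate_cohort <- function(n_animals, cfg = sim_config(), seed = 1) {
  stopifnot(is_count(n_animals))
  out <- lapply(seq_len(n_animals), function(i) {
    ci <- cfg
    ci$animal_id <- paste0("sow", i)
    simulate_sow(ci, seed = seed * 1000L + i)
  })
  stats::setNames(out, vapply(out, function(s) s$config$animal_id, ""))
}
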