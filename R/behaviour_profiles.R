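## Per-animal lying-behaviour profiles: posture time budgets,
## transition-frequency series, and per-feature ECDF comparisons against a
## pooled all-animal baseline.

TRANSITION_FEATURE_NAMES <- c("duration_s", "peak_accel", "accel_range",
                              "jerk", "pitch_rate", "roll_rate")

#' Posture time budget
#'
#' Proportion of classified frames spent in each of the five posture
#' classes; proportions sum to 1 and are invariant to the order of the
#' labels.
#'
#' @param labels Vector of posture labels (factor or character over
#'   [posture_classes()]).
#' @return Named numeric vector of five proportions.
#' @export
time_budget <- function(labels) {
  if (length(labels) == 0L)
    stop_sowmotion("time budget of zero labels is undefined",
                   "sowmotion_empty_input")
  tab <- table(factor(labels, levels = .POSTURES))
  stats::setNames(as.numeric(tab) / sum(tab), .POSTURES)
}

#' Transition-frequency series
#'
#' Counts transitions in a moving two-hour window stepped by 12 minutes
#' (defaults): for each window start `0, step_s, 2 step_s, ...` while the
#' full window fits in the span, the number of transition points inside the
#' half-open window `[start, start + window_s)` is reported at the window
#' centre. A span shorter than one window yields a single truncated window,
#' flagged via the `truncated` attribute.
#'
#' @param points Transition-point times in seconds.
#' @param span_s Trace span in seconds.
#' @param window_s,step_s Window length and step in seconds.
#' @return Data frame with `center_s` and `count`; attributes `window_s`,
#'   `step_s`, `truncated`.
#' @export
transition_frequency <- function(points, span_s, window_s = 7200,
                                 step_s = 720) {
  if (!is_scalar_num(window_s) || window_s <= 0 ||
      !is_scalar_num(step_s) || step_s <= 0)
    stop_sowmotion("window_s and step_s must be positive",
                   "sowmotion_config_error")
  truncated <- span_s < window_s
  if (truncated) {
    warning("span shorter than one window; returning a single truncated window",
            call. = FALSE)
    starts <- 0
    ends <- span_s
  } else {
    starts <- seq(0, span_s - window_s, by = step_s)
    ends <- starts + window_s
  }
  counts <- vapply(seq_along(starts), function(i)
    sum(points >= starts[i] & points < ends[i]), numeric(1))
  structure(data.frame(center_s = (starts + ends) / 2, count = counts),
            window_s = window_s, step_s = step_s, truncated = truncated)
}

feature_ecdfs <- function(features) {
  if (is.null(features) || nrow(features) == 0L) return(NULL)
  out <- lapply(TRANSITION_FEATURE_NAMES, function(nm)
    stats::ecdf(features[[nm]]))
  stats::setNames(out, TRANSITION_FEATURE_NAMES)
}

#' Per-animal lying-behaviour profiles
#'
#' For each animal, builds the posture time budget, the
#' transition-frequency series, and — for each of the six transition
#' features — the animal's empirical cumulative distribution function
#' (ECDF, `F(x)` = proportion of that animal's transitions with feature
#' value at most `x`) next to the pooled baseline ECDF over all animals'
#' transitions. By default the baseline includes the animal under
#' comparison; `leave_one_out = TRUE` excludes it.
#'
#' @param animals Named list, one entry per animal, each a list with
#'   elements `labels` (posture labels of its classified frames), `points`
#'   (transition times, seconds), `span_s` (trace span, seconds) and
#'   `features` (a [transition_features()] data frame).
#' @param window_s,step_s Passed to [transition_frequency()].
#' @param leave_one_out Exclude each animal from its own baseline.
#' @return Named list of class `behaviour_profiles`; each element (class
#'   `behaviour_profile`) has `animal_id`, `time_budget`,
#'   `transition_frequency`, `ecdf`, `baseline` and `n_transitions`.
#' @export
behaviour_profiles <- function(animals, window_s = 7200, step_s = 720,
                               leave_one_out = FALSE) {
  if (length(animals) < 1L)
    stop_sowmotion("at least one animal required", "sowmotion_empty_input")
  ids <- names(animals)
  if (is.null(ids)) ids <- as.character(seq_along(animals))
  all_feats <- do.call(rbind, lapply(seq_along(animals), function(i) {
    f <- animals[[i]]$features
    if (is.null(f) || nrow(f) == 0L) return(NULL)
    cbind(.animal = ids[i], f[, TRANSITION_FEATURE_NAMES, drop = FALSE])
  }))
  profiles <- lapply(seq_along(animals), function(i) {
    an <- animals[[i]]
    base_feats <- if (leave_one_out)
      all_feats[all_feats$.animal != ids[i], , drop = FALSE] else all_feats
    own <- an$features
    n_tr <- if (is.null(own)) 0L else nrow(own)
    if (n_tr == 0L)
      warning(sprintf("animal %s has no transitions; ECDFs omitted", ids[i]),
              call. = FALSE)
    structure(list(
      animal_id = ids[i],
      time_budget = time_budget(an$labels),
      transition_frequency = transition_frequency(an$points, an$span_s,
                                                  window_s, step_s),
      ecdf = feature_ecdfs(own),
      baseline = feature_ecdfs(base_feats),
      n_transitions = n_tr), class = "behaviour_profile")
  })
  structure(stats::setNames(profiles, ids), class = "behaviour_profiles")
}

#' @export
print.behaviour_profile <- function(x, ...) {
  cat(sprintf("<behaviour_profile> animal %s: %d transitions\n",
              x$animal_id, x$n_transitions))
  cat("time budget:\n")
  print(round(x$time_budget, 3))
  invisible(x)
}

#' Plot a behaviour profile
#'
#' `which = "ecdf"` draws the 2x3 grid of per-feature ECDFs (animal in
#' black, pooled baseline in blue); `which = "frequency"` draws the
#' transition-frequency series.
#'
#' @param x A `behaviour_profile`.
#' @param which `"ecdf"` or `"frequency"`.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.behaviour_profile <- function(x, which = c("ecdf", "frequency"), ...) {
  which <- match.arg(which)
  if (which == "frequency") {
    tf <- x$transition_frequency
    plot(tf$center_s / 3600, tf$count, type = "l",
         xlab = "time [h]", ylab = "transitions per 2 h window",
         main = paste("Transition frequency -", x$animal_id), ...)
    return(invisible(x))
  }
  if (is.null(x$ecdf)) {
    warning("no transitions; nothing to plot", call. = FALSE)
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in TRANSITION_FEATURE_NAMES) {
    plot(x$baseline[[nm]], col = "blue", main = nm, xlab = nm,
         ylab = "F(x)", do.points = FALSE, verticals = TRUE, ...)
    graphics::lines(x$ecdf[[nm]], col = "black", do.points = FALSE,
                    verticals = TRUE)
  }
  invisible(x)
}
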