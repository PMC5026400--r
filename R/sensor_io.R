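## Trace and annotation containers plus their CSV readers/writers.
##
## On-disk trace format: optional comment header lines
##   # rate_hz=<r>
##   # animal_id=<id>
## followed by a CSV with columns (time_s,)x,y,z, one row per sample.
## Annotation format: CSV with columns track,label,start_s,end_s where track
## is "posture" or "transition"; transition rows leave label empty.

#' Construct a tri-axial acceleration trace
#'
#' A `signal_trace` holds a uniformly sampled tri-axial accelerometer series
#' in units of standard gravity (g0). Sample `k` (1-based) is at time
#' `(k - 1) / rate_hz` seconds from trace start. The sensor records in the
#' range ±8 g0; values outside that range are clipped (sensor saturation)
#' with a warning counting the affected samples.
#'
#' Axis convention (sensor on the sow's hind-end): `x` craniocaudal,
#' `y` mediolateral, `z` dorsoventral.
#'
#' @param x,y,z Numeric vectors of equal length, acceleration in g0.
#' @param rate_hz Sampling rate in Hz (nominally 100).
#' @param animal_id Identifier for the animal the trace was recorded from.
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(x, y, z, rate_hz, animal_id = "unknown") {
  if (!is_scalar_num(rate_hz) || rate_hz <= 0)
    stop_sowmotion("rate_hz must be a positive number", "sowmotion_format_error")
  n <- length(x)
  if (n < 1L)
    stop_sowmotion("trace must contain at least one sample",
                   "sowmotion_empty_input")
  if (length(y) != n || length(z) != n)
    stop_sowmotion("x, y, z must have equal length", "sowmotion_format_error")
  x <- as.double(x); y <- as.double(y); z <- as.double(z)
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop_sowmotion("trace contains missing values", "sowmotion_format_error")
  n_clip <- sum(abs(x) > 8) + sum(abs(y) > 8) + sum(abs(z) > 8)
  if (n_clip > 0L) {
    x <- pmin(pmax(x, -8), 8)
    y <- pmin(pmax(y, -8), 8)
    z <- pmin(pmax(z, -8), 8)
    warning(sprintf("%d sample value(s) outside ±8 g0 clipped", n_clip),
            call. = FALSE)
  }
  structure(
    list(animal_id = as.character(animal_id), rate_hz = as.double(rate_hz),
         x = x, y = y, z = z),
    class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> animal %s: %d samples at %g Hz (%.2f h)\n",
              x$animal_id, n_samples(x), x$rate_hz,
              trace_duration_s(x) / 3600))
  invisible(x)
}

#' Number of samples and duration of a trace
#'
#' @param trace A `signal_trace`.
#' @return `n_samples()`: integer sample count. `trace_duration_s()`: trace
#'   duration in seconds (`count / rate`).
#' @export
n_samples <- function(trace) length(trace$x)

#' @rdname n_samples
#' @export
trace_duration_s <- function(trace) n_samples(trace) / trace$rate_hz

#' Sample times of a trace
#' @param trace A `signal_trace`.
#' @return Seconds from trace start, one per sample.
#' @export
trace_times <- function(trace) (seq_len(n_samples(trace)) - 1) / trace$rate_hz

#' Construct an annotation track
#'
#' Ground-truth labelled intervals for one animal: posture-state intervals
#' (labelled with one of the five posture classes, see [posture_classes()])
#' and unlabelled posture-transition intervals. Within each track the
#' intervals must be non-overlapping with `start < end`.
#'
#' @param animal_id Animal identifier.
#' @param postures Data frame with columns `start_s`, `end_s`, `label`.
#' @param transitions Data frame with columns `start_s`, `end_s`.
#' @param offset_s Constant shift (seconds) added to all annotation times,
#'   for traces whose clock origin differs from the annotations'.
#' @return An object of class `annotation_track`.
#' @export
annotation_track <- function(animal_id, postures, transitions, offset_s = 0) {
  postures <- as.data.frame(postures)
  transitions <- as.data.frame(transitions)
  if (nrow(postures) == 0L)
    postures <- data.frame(start_s = numeric(), end_s = numeric(),
                           label = character())
  if (nrow(transitions) == 0L)
    transitions <- data.frame(start_s = numeric(), end_s = numeric())
  postures$start_s <- as.double(postures$start_s) + offset_s
  postures$end_s <- as.double(postures$end_s) + offset_s
  transitions$start_s <- as.double(transitions$start_s) + offset_s
  transitions$end_s <- as.double(transitions$end_s) + offset_s
  postures$label <- as.character(postures$label)

  bad <- setdiff(unique(postures$label), .POSTURES)
  if (length(bad) > 0L)
    stop_sowmotion(
      paste0("unknown posture label(s): ", paste(bad, collapse = ", "),
             " (allowed: ", paste(.POSTURES, collapse = ", "),
             "; kneeling is transitory and has no class)"),
      "sowmotion_label_error")
  check_intervals <- function(df, what) {
    if (nrow(df) == 0L) return(df)
    if (any(!is.finite(df$start_s)) || any(!is.finite(df$end_s)))
      stop_sowmotion(paste0("non-finite ", what, " interval bounds"),
                     "sowmotion_interval_error")
    if (any(df$start_s >= df$end_s))
      stop_sowmotion(paste0(what, " interval with start >= end"),
                     "sowmotion_interval_error")
    df <- df[order(df$start_s), , drop = FALSE]
    if (nrow(df) > 1L &&
        any(df$start_s[-1L] < df$end_s[-nrow(df)] - 1e-9))
      stop_sowmotion(paste0("overlapping ", what, " intervals"),
                     "sowmotion_overlap_error")
    rownames(df) <- NULL
    df
  }
  postures <- check_intervals(postures, "posture")
  transitions <- check_intervals(transitions, "transition")
  structure(list(animal_id = as.character(animal_id),
                 postures = postures, transitions = transitions),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> animal %s: %d posture, %d transition interval(s)\n",
              x$animal_id, nrow(x$postures), nrow(x$transitions)))
  invisible(x)
}

read_header_meta <- function(lines) {
  meta <- list()
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$", h))[[1]]
    if (length(m) == 3L) meta[[m[2L]]] <- m[3L]
  }
  meta
}

#' Read an accelerometer trace from CSV
#'
#' Expects a CSV with columns `x,y,z` or `time_s,x,y,z` and optional comment
#' header lines `# rate_hz=<r>` and `# animal_id=<id>`. The sampling rate is
#' taken from `rate`, the metadata header, or (failing both) the median time
#' step. When a time column is present its steps must be uniform to within a
#' quarter of a sample period, otherwise a sampling error is raised.
#'
#' @param path Path to the CSV file.
#' @param rate Sampling rate in Hz; overrides any file metadata.
#' @param animal_id Optional animal id; overrides any file metadata.
#' @return A [signal_trace()].
#' @export
read_trace <- function(path, rate = NULL, animal_id = NULL) {
  if (!file.exists(path))
    stop_sowmotion(paste0("file not found: ", path), "sowmotion_format_error")
  lines <- readLines(path, warn = FALSE)
  meta <- read_header_meta(lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L)
    stop_sowmotion("empty trace file", "sowmotion_empty_input")
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        header = grepl("[A-Za-z]", body[1L]))
  if (!grepl("[A-Za-z]", body[1L])) {
    names(df) <- if (ncol(df) == 4L) c("time_s", "x", "y", "z")
                 else if (ncol(df) == 3L) c("x", "y", "z")
                 else names(df)
  }
  if (!all(c("x", "y", "z") %in% names(df)))
    stop_sowmotion("trace file must have columns x, y, z (optionally time_s)",
                   "sowmotion_format_error")
  if (is.null(rate) && !is.null(meta$rate_hz)) rate <- as.numeric(meta$rate_hz)
  if (is.null(rate) && "time_s" %in% names(df) && nrow(df) >= 2L)
    rate <- 1 / stats::median(diff(df$time_s))
  if (is.null(rate))
    stop_sowmotion("sampling rate unavailable: pass `rate` or add a '# rate_hz=' header",
                   "sowmotion_format_error")
  if ("time_s" %in% names(df) && nrow(df) >= 2L) {
    dt <- diff(df$time_s)
    if (any(abs(dt - 1 / rate) > 0.25 / rate))
      stop_sowmotion("non-uniform timestamps beyond tolerance",
                     "sowmotion_sampling_error")
  }
  if (is.null(animal_id))
    animal_id <- if (!is.null(meta$animal_id)) meta$animal_id else "unknown"
  signal_trace(df$x, df$y, df$z, rate_hz = rate, animal_id = animal_id)
}

#' Write an accelerometer trace to CSV
#'
#' Writes the metadata header (`# rate_hz=`, `# animal_id=`) and one
#' `time_s,x,y,z` row per sample with six decimal places, so that
#' `read_trace(write_trace(...))` round-trips to 1e-6.
#'
#' @param trace A [signal_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "signal_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rate_hz=%.10g", trace$rate_hz),
               sprintf("# animal_id=%s", trace$animal_id),
               "time_s,x,y,z"), con)
  writeLines(sprintf("%.6f,%.6f,%.6f,%.6f",
                     trace_times(trace), trace$x, trace$y, trace$z), con)
  invisible(path)
}

#' Read interval annotations from CSV
#'
#' Expects columns `track,label,start_s,end_s` with `track` equal to
#' `"posture"` or `"transition"`; an optional `# animal_id=` header names the
#' animal. Label, interval and overlap errors follow [annotation_track()].
#'
#' @param path Path to the CSV file.
#' @param animal_id Optional animal id override.
#' @param offset_s Constant shift applied to all annotation times.
#' @return An [annotation_track()].
#' @export
read_annotations <- function(path, animal_id = NULL, offset_s = 0) {
  if (!file.exists(path))
    stop_sowmotion(paste0("file not found: ", path), "sowmotion_format_error")
  lines <- readLines(path, warn = FALSE)
  meta <- read_header_meta(lines)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L)
    stop_sowmotion("empty annotation file", "sowmotion_empty_input")
  has_header <- grepl("^\\s*track\\s*,", body[1L])
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        header = has_header,
                        colClasses = c("character", "character",
                                       "numeric", "numeric"))
  if (!has_header) names(df) <- c("track", "label", "start_s", "end_s")
  if (!all(c("track", "label", "start_s", "end_s") %in% names(df)))
    stop_sowmotion("annotation file must have columns track,label,start_s,end_s",
                   "sowmotion_format_error")
  if (is.null(animal_id))
    animal_id <- if (!is.null(meta$animal_id)) meta$animal_id else "unknown"
  bad_track <- setdiff(unique(df$track), c("posture", "transition"))
  if (length(bad_track) > 0L)
    stop_sowmotion(paste0("unknown track type(s): ",
                          paste(bad_track, collapse = ", ")),
                   "sowmotion_format_error")
  pos <- df[df$track == "posture", c("start_s", "end_s", "label")]
  tra <- df[df$track == "transition", c("start_s", "end_s")]
  annotation_track(animal_id, pos, tra, offset_s = offset_s)
}

#' Write interval annotations to CSV
#'
#' @param track An [annotation_track()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(track, path) {
  stopifnot(inherits(track, "annotation_track"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# animal_id=%s", track$animal_id),
               "track,label,start_s,end_s"), con)
  if (nrow(track$postures) > 0L)
    writeLines(sprintf("posture,%s,%.6f,%.6f", track$postures$label,
                       track$postures$start_s, track$postures$end_s), con)
  if (nrow(track$transitions) > 0L)
    writeLines(sprintf("transition,,%.6f,%.6f",
                       track$transitions$start_s, track$transitions$end_s), con)
  invisible(path)
}
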