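## End-to-end pipeline: features -> detection/segmentation -> (optional)
## classification -> transition features -> behaviour profiles -> (optional)
## event evaluation, with a YAML run configuration and a reproducible
## manifest.

#' Default run configuration
#'
#' Nested list mirroring the stage configurations ([filter_config()],
#' [frame_config()], [detection_config()], the classifier grid,
#' [match_events()] tolerance, the profile windows and [sim_config()]),
#' plus a global `seed`. [read_run_config()] overlays a YAML file on these
#' defaults, so a bare run is fully specified.
#'
#' @return Named nested list.
#' @export
default_run_config <- function() {
  dc <- detection_config()
  list(
    seed = 1L,
    filter = list(alpha = 0.01, initial_state = "first_sample",
                  literal_sign = FALSE),
    frame = list(seconds = 2),
    detect = list(theta_p = dc$theta_p, theta_r = dc$theta_r,
                  group_size = dc$group_size,
                  overlap_fraction = dc$overlap_fraction,
                  confirm_adjacent = dc$confirm_adjacent,
                  stabilization_window_s = dc$stabilization_window_s,
                  stability_tol_p = dc$stability_tol_p,
                  stability_tol_r = dc$stability_tol_r),
    classify = list(cost = default_svm_grid()$cost,
                    gamma = default_svm_grid()$gamma,
                    cv_folds = 3, tune_max_per_class = 400,
                    fit_max_per_class = 2000, class_weights = FALSE),
    evaluate = list(tolerance_s = 2),
    profile = list(window_s = 7200, step_s = 720, leave_one_out = FALSE),
    simulate = list(duration_h = 24, rate_hz = 100))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; values are validated by constructing the
#' corresponding stage configuration objects.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0L)
      stop_sowmotion(paste0("unknown config section(s): ",
                            paste(unknown, collapse = ", ")),
                     "sowmotion_config_error")
    cfg <- merge_config(cfg, user)
  }
  ## validation by construction
  run_filter_config(cfg)
  run_frame_config(cfg)
  run_detection_config(cfg)
  if (cfg$evaluate$tolerance_s < 0)
    stop_sowmotion("evaluate.tolerance_s must be non-negative",
                   "sowmotion_config_error")
  cfg
}

run_filter_config <- function(cfg)
  filter_config(cfg$filter$alpha, cfg$filter$initial_state,
                cfg$filter$literal_sign)
run_frame_config <- function(cfg) frame_config(cfg$frame$seconds)
run_detection_config <- function(cfg)
  detection_config(cfg$detect$theta_p, cfg$detect$theta_r,
                   cfg$detect$group_size, cfg$detect$overlap_fraction,
                   cfg$detect$confirm_adjacent,
                   cfg$detect$stabilization_window_s,
                   cfg$detect$stability_tol_p, cfg$detect$stability_tol_r)

write_stage_csv <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' For each input trace: extracts features, detects and segments posture
#' transitions and computes their kinematic descriptors. When annotations
#' are supplied the frames are labelled, the detector is evaluated
#' event-wise, and with at least two annotated animals the posture
#' classifier is evaluated leave-one-pig-out; behaviour profiles are then
#' built from the annotated (or, without annotations, the detected)
#' information. All intermediate tables are written as CSV, the summary as
#' JSON, and a manifest records the configuration, seed and package version
#' so identical inputs reproduce identical outputs.
#'
#' @param trace_paths Character vector of trace CSV paths.
#' @param out_dir Output directory (created if needed).
#' @param config A configuration list from [read_run_config()], or a YAML
#'   path, or `NULL` for defaults.
#' @param annotation_paths Optional annotation CSV paths, parallel to
#'   `trace_paths`.
#' @return The report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(trace_paths, out_dir, config = NULL,
                         annotation_paths = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config)) config <- default_run_config()
  fcfg <- run_filter_config(config)
  wcfg <- run_frame_config(config)
  dcfg <- run_detection_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop_sowmotion(sprintf("stage '%s' failed: %s", stage,
                             conditionMessage(e)),
                     "sowmotion_pipeline_error"))
  }
  have_ann <- !is.null(annotation_paths)
  if (have_ann && length(annotation_paths) != length(trace_paths))
    stop_sowmotion("one annotation file per trace required",
                   "sowmotion_pipeline_error")

  per_animal <- list()
  labelled <- list()
  report <- list(animals = list())
  for (i in seq_along(trace_paths)) {
    trace <- with_stage("read", read_trace(trace_paths[i]))
    id <- trace$animal_id
    frames <- with_stage("features", extract_features(trace, fcfg, wcfg))
    segs <- with_stage("detect", detect_and_segment(trace, fcfg, wcfg, dcfg))
    tfeat <- with_stage("transition_features",
                        transition_features(segs, trace, frames))
    write_stage_csv(frames[, c("frame", "start_s", "end_s", "p", "r", "a")],
                    file.path(out_dir, paste0(id, "_features.csv")))
    write_stage_csv(segs, file.path(out_dir, paste0(id, "_segments.csv")))
    write_stage_csv(tfeat, file.path(out_dir, paste0(id, "_tfeatures.csv")))
    animal_report <- list(n_frames = nrow(frames), n_detected = nrow(segs))
    ann <- NULL
    if (have_ann) {
      ann <- with_stage("read", read_annotations(annotation_paths[i],
                                                 animal_id = id))
      lf <- with_stage("label", label_frames(frames, ann))
      labelled[[id]] <- lf
      counts <- with_stage("evaluate",
                           match_events(segs, ann,
                                        config$evaluate$tolerance_s))
      pr <- tryCatch(precision(counts), error = function(e) NA_real_)
      rc <- tryCatch(recall(counts), error = function(e) NA_real_)
      animal_report$event_counts <- list(tp = counts$tp, fp = counts$fp,
                                         fn = counts$fn)
      animal_report$precision <- pr
      animal_report$recall <- rc
      animal_report$f1 <- if (is.na(pr) || is.na(rc)) NA_real_ else f1(pr, rc)
    }
    per_animal[[id]] <- list(
      labels = if (have_ann) labelled[[id]]$label else NULL,
      points = segs$point_s, span_s = trace_duration_s(trace),
      features = tfeat)
    report$animals[[id]] <- animal_report
  }

  if (length(labelled) >= 2L) {
    lopo <- with_stage("classify",
                       lopo_evaluate(labelled,
                                     grid = list(cost = config$classify$cost,
                                                 gamma = config$classify$gamma),
                                     seed = config$seed,
                                     cv_folds = config$classify$cv_folds,
                                     tune_max_per_class = config$classify$tune_max_per_class,
                                     fit_max_per_class = config$classify$fit_max_per_class,
                                     class_weights = config$classify$class_weights))
    report$classification <- list(
      per_class_f1 = as.list(round(lopo$per_class_f1, 6)),
      mean_f1 = lopo$mean_f1,
      confusion = as.data.frame.matrix(lopo$confusion))
  }

  if (have_ann) {
    profs <- with_stage("profile", behaviour_profiles(
      per_animal,
      window_s = config$profile$window_s, step_s = config$profile$step_s,
      leave_one_out = config$profile$leave_one_out))
    report$profiles <- lapply(profs, function(p) list(
      time_budget = as.list(p$time_budget),
      n_transitions = p$n_transitions))
    for (id in names(profs))
      write_stage_csv(profs[[id]]$transition_frequency,
                      file.path(out_dir, paste0(id, "_frequency.csv")))
  } else {
    ## no posture labels without annotations: emit the frequency series only
    for (id in names(per_animal)) {
      tf <- with_stage("profile",
                       transition_frequency(per_animal[[id]]$points,
                                            per_animal[[id]]$span_s,
                                            config$profile$window_s,
                                            config$profile$step_s))
      write_stage_csv(tf, file.path(out_dir, paste0(id, "_frequency.csv")))
    }
  }

  manifest <- list(
    package = "sowmotion",
    version = as.character(utils::packageVersion("sowmotion")),
    seed = config$seed,
    config = config,
    inputs = basename(trace_paths))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
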