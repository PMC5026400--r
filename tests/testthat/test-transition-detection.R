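test_that("extended frames span the stated groups with a whole-frame stride", {
  set.seed(1)
  fr <- random_frames(12)
  cfg <- detection_config(group_size = 6, overlap_fraction = 0.6)
  ext <- build_extended_frames(fr, cfg)
  ## stride = round(6 * 0.4) = 2 base frames -> starts at frames 1,3,5,7
  expect_equal(nrow(ext), 4L)
  expect_equal(ext$start_s, c(0, 4, 8, 12))
  expect_equal(ext$end_s, c(12, 16, 20, 24))

  ## group_size 1 with no overlap is the identity configuration
  id_cfg <- detection_config(group_size = 1, overlap_fraction = 0)
  ext1 <- build_extended_frames(fr, id_cfg)
  expect_equal(nrow(ext1), nrow(fr))
  expect_equal(ext1$p, fr$p)
  expect_equal(ext1$r, fr$r)
  expect_equal(ext1$a, fr$a)

  ## constant orientation collapses to identical extended orientations
  cfr <- random_frames(12)
  cfr$gx <- 0; cfr$gy <- 0.3; cfr$gz <- 0.9
  ext2 <- build_extended_frames(cfr, cfg)
  expect_true(all(abs(diff(ext2$p)) < 1e-12))
  expect_true(all(abs(diff(ext2$r)) < 1e-12))

  expect_error(build_extended_frames(fr[1:3, ], cfg),
               class = "sowmotion_empty_input")
})

test_that("threshold rule detects sustained changes and rejects spikes", {
  mk_ext <- function(p, step = 4) {
    n <- length(p)
    structure(data.frame(frame = 1:n, start_s = (0:(n - 1)) * step,
                         end_s = (0:(n - 1)) * step + 12,
                         p = p, r = 0, a = 0.01,
                         gx = 0, gy = 0, gz = 1, m1 = 1, m2 = 1),
              class = c("feature_frames", "data.frame"), frame_step_s = step)
  }
  cfg <- detection_config(theta_p = 10, theta_r = 10)

  ## constant orientation: nothing to detect
  expect_length(detect_transition_points(mk_ext(rep(5, 10)), cfg), 0L)

  ## sustained pitch change: one collapsed point at the first exceeding
  ## pair's midpoint
  p <- c(0, 0, 0, 15, 30, 45, 45, 45)
  pts <- detect_transition_points(mk_ext(p), cfg)
  expect_length(pts, 1L)
  cen <- (mk_ext(p)$start_s + mk_ext(p)$end_s) / 2
  expect_equal(pts, (cen[3] + cen[4]) / 2)
  expect_equal(pts, oracle_detect(mk_ext(p), cfg))

  ## a change exceeding the threshold in a single frame pair, with both
  ## neighbouring pairs stable: a temporary adjustment of position, not a
  ## transition (true posture changes always light up >= 2 consecutive
  ## pairs because extended frames overlap)
  spike <- c(0, 0, 0, 12, 12, 12, 12)
  expect_length(detect_transition_points(mk_ext(spike), cfg), 0L)
  expect_length(oracle_detect(mk_ext(spike), cfg), 0L)
})

test_that("detection agrees exactly with brute-force pair enumeration", {
  set.seed(42)
  cfgs <- list(detection_config(theta_p = 10, theta_r = 12),
               detection_config(theta_p = 6, theta_r = 6,
                                confirm_adjacent = 2),
               detection_config(theta_p = 20, theta_r = 8, group_size = 3,
                                overlap_fraction = 0.4))
  for (i in 1:60) {
    fr <- random_frames(sample(8:150, 1))
    cfg <- cfgs[[1 + i %% length(cfgs)]]
    if (nrow(fr) < cfg$group_size + 1) next
    ext <- build_extended_frames(fr, cfg)
    if (nrow(ext) < 2) next
    expect_identical(detect_transition_points(ext, cfg),
                     oracle_detect(ext, cfg))
  }
})

test_that("detection counts are monotone non-increasing in the thresholds", {
  ## candidacy and confirmation are pointwise monotone in the thresholds,
  ## so the set of confirmed pairs shrinks as thresholds rise (run-collapsed
  ## event counts can split and are checked only through the pair sets)
  set.seed(17)
  cfg0 <- detection_config()
  for (rep in 1:10) {
    fr <- random_frames(120)
    ext <- build_extended_frames(fr, cfg0)
    prev <- rep(TRUE, nrow(ext) - 1)
    for (th in c(4, 8, 16, 32)) {
      conf <- confirmed_pairs(ext, th)
      expect_false(any(conf & !prev))  # subset of the lower-threshold set
      prev <- conf
    }
  }
})

test_that("detection is equivariant to time translation", {
  set.seed(23)
  fr <- random_frames(80)
  cfg <- detection_config(theta_p = 8, theta_r = 8)
  ext <- build_extended_frames(fr, cfg)
  pts <- detect_transition_points(ext, cfg)
  shift <- 123.5
  fr2 <- fr
  fr2$start_s <- fr$start_s + shift
  fr2$end_s <- fr$end_s + shift
  ext2 <- build_extended_frames(fr2, cfg)
  pts2 <- detect_transition_points(ext2, cfg)
  expect_equal(pts2, pts + shift)
  if (length(pts) > 0) {
    seg <- segment_transition(fr, pts[1], cfg)
    seg2 <- segment_transition(fr2, pts[1] + shift, cfg)
    expect_equal(seg2$start_s, seg$start_s + shift)
    expect_equal(seg2$end_s, seg$end_s + shift)
  }
})

test_that("segmentation brackets a step between two stable plateaus", {
  ## step change at t = 40 s between long constant plateaus
  tr <- orientation_trace(data.frame(dur_s = c(40, 40),
                                     pitch = c(0, 0), roll = c(0, 80)))
  fr <- extract_features(tr)
  cfg <- detection_config()
  seg <- segment_transition(fr, 40, cfg)
  expect_false(seg$truncated)
  expect_lt(seg$start_s, 40)
  expect_gt(seg$end_s, 40)
  ## tight bracket: within one frame + stabilization window of the step
  expect_gte(seg$start_s, 40 - 2 - cfg$stabilization_window_s - 2)
  expect_lte(seg$end_s, 40 + 2 + cfg$stabilization_window_s + 2)
})

test_that("segmentation recovers a known ramp interval", {
  ## pitch ramps 0 -> 40 during t in [10, 16], constant elsewhere
  tr <- orientation_trace(data.frame(dur_s = c(10, 30),
                                     pitch = c(0, 40), roll = c(0, 0)),
                          ramp_s = 6)
  fr <- extract_features(tr)
  seg <- segment_transition(fr, 13, detection_config())
  expect_gte(seg$start_s, 8); expect_lte(seg$start_s, 11)
  expect_gte(seg$end_s, 15); expect_lte(seg$end_s, 18)
})

test_that("segmentation at the trace edge is flagged truncated", {
  ## only 2 s of pre-transition plateau: shorter than the stabilization
  ## window, so no consistent window exists on the left side
  tr <- orientation_trace(data.frame(dur_s = c(2, 30),
                                     pitch = c(0, 40), roll = c(0, 0)),
                          ramp_s = 4)
  fr <- extract_features(tr)
  seg <- segment_transition(fr, 3, detection_config())
  expect_true(seg$truncated)
  expect_equal(seg$start_s, 0)
  expect_error(segment_transition(fr, 1e6, detection_config()),
               class = "sowmotion_interval_error")
})

test_that("full detection pipeline recovers planted transitions", {
  sim <- simulate_sow(sim_config(duration_h = 2), seed = 3)
  segs <- detect_and_segment(sim$trace)
  truth <- sim$truth$transitions
  ## every truth transition is overlapped by a detected segment and vice
  ## versa (clean signal, well-separated transitions)
  counts <- match_events(segs, truth, tolerance_s = 2)
  expect_equal(counts$fn, 0L)
  expect_equal(counts$fp, 0L)
  expect_equal(counts$tp, nrow(truth))
  ## segments are ordered, non-overlapping, and bracket their points
  expect_true(all(diff(segs$start_s) > 0))
  expect_true(all(segs$start_s[-1] >= segs$end_s[-nrow(segs)]))
  expect_true(all(segs$start_s <= segs$point_s & segs$point_s <= segs$end_s))
})

test_that("motionless and sub-threshold drifting traces yield no detections", {
  still <- signal_trace(rep(0, 9000), rep(0, 9000), rep(1, 9000), 100)
  expect_equal(nrow(detect_and_segment(still)), 0L)

  ## 5-minute gradual drift: 30 degrees of roll spread over 300 s changes
  ## each extended-frame pair by ~0.4 degrees, far below threshold -- the
  ## documented false-negative mode for very slow posture changes
  n <- 30000
  r_drift <- seq(0, 30, length.out = n)
  g <- invert_orientation(rep(0, n), r_drift)
  drift <- signal_trace(g[, 1], g[, 2], g[, 3], 100)
  expect_equal(nrow(detect_and_segment(drift)), 0L)
})
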