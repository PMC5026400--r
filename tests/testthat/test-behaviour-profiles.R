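test_that("time budgets are proportions that sum to one", {
  tb <- time_budget(rep(c("LL", "RL"), each = 50))
  expect_equal(tb, c(ST = 0, S = 0, LL = 0.5, RL = 0.5, SL = 0))
  expect_equal(time_budget(rep("ST", 7)),
               c(ST = 1, S = 0, LL = 0, RL = 0, SL = 0))
  expect_error(time_budget(character()), class = "sowmotion_empty_input")

  set.seed(14)
  labs <- sample(posture_classes(), 500, replace = TRUE,
                 prob = c(0.3, 0.05, 0.3, 0.25, 0.1))
  expect_equal(sum(time_budget(labs)), 1, tolerance = 1e-9)
  ## permutation invariance
  expect_identical(time_budget(labs), time_budget(sample(labs)))
})

test_that("simulated dwell ratios are recovered by the time budget", {
  ## dwell means 2:1 for LL:RL (others rare) -> budget ratio ~2:1
  cfg <- sim_config(duration_h = 24)
  cfg$dwell_mean_s <- c(ST = 100, S = 61, LL = 1200, RL = 600, SL = 100)
  sched <- simulate_schedule(cfg, seed = 19)
  pos <- sched$postures
  tot <- tapply(pos$end_s - pos$start_s, pos$label, sum)
  expect_equal(unname(tot[["LL"]] / tot[["RL"]]), 2, tolerance = 0.35)
})

test_that("transition-frequency windows count half-open intervals", {
  ## no transitions -> all-zero series over the full span
  tf0 <- transition_frequency(numeric(0), 24 * 3600)
  expect_true(all(tf0$count == 0))
  expect_equal(nrow(tf0), length(seq(0, 24 * 3600 - 7200, by = 720)))

  ## 10 transitions inside hour 5 of a 24-h span: every window covering
  ## hour 5 counts 10, all others 0 (brute-force interval oracle)
  pts <- seq(5 * 3600 + 100, 5 * 3600 + 3500, length.out = 10)
  tf <- transition_frequency(pts, 24 * 3600)
  starts <- tf$center_s - 3600
  oracle <- vapply(starts, function(s)
    sum(pts >= s & pts < s + 7200), numeric(1))
  expect_equal(tf$count, oracle)
  covering <- starts <= 5 * 3600 + 100 & starts + 7200 > 5 * 3600 + 3500
  expect_true(all(tf$count[covering] == 10))
  expect_true(all(tf$count[!covering] %in% 0:10))
  expect_true(any(tf$count == 0))

  ## disjoint windows conserve the total count
  tfd <- transition_frequency(pts, 24 * 3600, window_s = 7200,
                              step_s = 7200)
  expect_equal(sum(tfd$count), sum(pts < max(tfd$center_s) + 3600))

  ## span shorter than a window: single truncated window, flagged
  expect_warning(tft <- transition_frequency(c(10, 20), 100), "truncated")
  expect_equal(nrow(tft), 1L)
  expect_equal(tft$count, 2)
  expect_true(attr(tft, "truncated"))
})

test_that("profile ECDFs follow the cumulative-proportion definition", {
  F <- stats::ecdf(c(1, 2, 3))
  expect_equal(F(2), 2 / 3)
  expect_equal(F(0.999), 0)
  expect_equal(F(3), 1)

  mk_feat <- function(n, scale = 1, seed) {
    set.seed(seed)
    data.frame(duration_s = scale * stats::rexp(n, 1 / 8) + 1,
               peak_accel = stats::runif(n, 1, 4),
               accel_range = stats::runif(n, 0, 2),
               jerk = stats::rexp(n, 1), pitch_rate = stats::rexp(n, 1),
               roll_rate = stats::rexp(n, 1))
  }
  animals <- list(
    a1 = list(labels = rep("LL", 10), points = c(100, 200), span_s = 7200,
              features = mk_feat(40, seed = 1)),
    a2 = list(labels = rep("RL", 10), points = c(300), span_s = 7200,
              features = mk_feat(60, seed = 2)))
  profs <- behaviour_profiles(animals)
  expect_named(profs, c("a1", "a2"))

  ## every ECDF is a nondecreasing step function from 0 to 1
  for (p in profs) for (nm in names(p$ecdf)) {
    F <- p$ecdf[[nm]]
    kn <- stats::knots(F)
    expect_true(all(diff(F(kn)) >= 0))
    expect_equal(F(max(kn)), 1)
    expect_equal(F(min(kn) - 1e-9), 0)
  }

  ## pooled baseline is the transition-count-weighted mixture of the
  ## per-animal ECDFs (exact identity on a grid)
  grid <- seq(0, 10, by = 0.25)
  base <- profs$a1$baseline$duration_s
  mix <- (40 * profs$a1$ecdf$duration_s(grid) +
            60 * profs$a2$ecdf$duration_s(grid)) / 100
  expect_equal(base(grid), mix)

  ## single animal: own ECDF equals the baseline exactly
  solo <- behaviour_profiles(animals[1])
  expect_equal(solo$a1$ecdf$jerk(grid), solo$a1$baseline$jerk(grid))

  ## an animal with no transitions is flagged and gets no ECDFs
  animals$a3 <- list(labels = rep("ST", 5), points = numeric(0),
                     span_s = 7200, features = NULL)
  expect_warning(profs3 <- behaviour_profiles(animals), "no transitions")
  expect_null(profs3$a3$ecdf)
})

test_that("a short-transition animal's duration ECDF dominates the baseline", {
  mk <- function(n, rate, seed) {
    set.seed(seed)
    data.frame(duration_s = stats::rexp(n, rate) + 2,
               peak_accel = 1, accel_range = 1, jerk = 1,
               pitch_rate = 1, roll_rate = 1)
  }
  animals <- list(
    quick = list(labels = "LL", points = 1, span_s = 7200,
                 features = mk(300, rate = 1 / 4, seed = 3)),
    slow = list(labels = "LL", points = 1, span_s = 7200,
                features = mk(300, rate = 1 / 12, seed = 4)))
  profs <- behaviour_profiles(animals)
  grid <- seq(3, 30, by = 1)
  quick_F <- profs$quick$ecdf$duration_s(grid)
  base_F <- profs$quick$baseline$duration_s(grid)
  ## larger proportion of short durations: curve sits above the baseline
  expect_true(all(quick_F >= base_F))
  expect_gt(max(quick_F - base_F), 0.1)
})
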