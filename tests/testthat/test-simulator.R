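test_that("cohort generation is seed-reproducible and hits the baseline target", {
  co1 <- generate_cohort(100, seed = 5)
  co2 <- generate_cohort(100, seed = 5)
  expect_identical(co1, co2)
  expect_false(identical(co1, generate_cohort(100, seed = 6)))
  one <- generate_cohort(1, seed = 5)
  expect_equal(nrow(one), 1)
  # median of simulated baseline-period means near 10,000 steps/day
  cfg <- tiny_sim_config()
  bm <- vapply(seq_len(100), function(i) {
    simulate_user_weeks(co1[i, ], weeks = 1, seed = 300 + i, config = cfg)$baseline_mean
  }, numeric(1))
  expect_gt(stats::median(bm), 9000)
  expect_lt(stats::median(bm), 11000)
  expect_lt(abs(stats::median(bm) - 10000) / 10000, 0.10)
})

test_that("trajectories are deterministic under a fixed seed", {
  user <- generate_cohort(1, seed = 2)[1, ]
  a <- simulate_user_weeks(user, weeks = 4, seed = 9)
  b <- simulate_user_weeks(user, weeks = 4, seed = 9)
  expect_identical(a$records, b$records)
  expect_identical(a$goals, b$goals)
  co <- generate_cohort(4, seed = 3)
  t1 <- run_trial(co, seed = 77, weeks = 3)
  t2 <- run_trial(co, seed = 77, weeks = 3)
  expect_identical(t1$records, t2$records)
  expect_identical(t1$questionnaires, t2$questionnaires)
})

test_that("a null engine (responsiveness 0) leaves intervention steps at baseline", {
  cfg <- tiny_sim_config(responsiveness = 0, wear_prob = 1)
  co <- generate_cohort(100, cfg, seed = 8)
  deltas <- vapply(seq_len(100), function(i) {
    res <- simulate_user_weeks(co[i, ], weeks = 4, seed = 400 + i, config = cfg)
    rec <- res$records
    p0 <- clean_step_series(window_period(rec, standard_periods()$P0b))
    iv <- clean_step_series(window_period(rec, intervention_weeks(1, 4)))
    mean(iv$steps) - mean(p0$steps)
  }, numeric(1))
  expect_lt(abs(stats::median(deltas)), 300)
})

test_that("non-wear days appear at the configured rate", {
  cfg <- tiny_sim_config(wear_prob = 0.9)
  co <- generate_cohort(50, cfg, seed = 12)
  worn <- unlist(lapply(seq_len(50), function(i) {
    simulate_user_weeks(co[i, ], weeks = 4, seed = 500 + i, config = cfg)$records$worn
  }))
  frac <- mean(worn %in% FALSE)
  n <- length(worn)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n) + 0.005)
})

test_that("with noise off and ample capability the goal trace is the pure 500-step ladder", {
  cfg <- tiny_sim_config(
    within_log_sd = 0, wear_prob = 1, conf_slope = 0, conf_noise_sd = 0,
    responsiveness = 1e5, drive_slope = 5, efficacy_scale = 1,
    mastery_gain = 0 # keep confidence fixed inside the 70-90 band
  )
  user <- generate_cohort(1, cfg, seed = 1)[1, ]
  user$baseline_log_mean <- log(10000)
  user$baseline_log_sd <- 0
  user$self_efficacy <- 80
  res <- simulate_user_weeks(user, weeks = 12, seed = 1, config = cfg)
  expect_equal(res$goals$goal, pmin(10500 + 500 * (0:11), 15000))
  expect_true(all(res$goals$days_achieved == 7))
})

test_that("self-efficacy stays within [0, 100] along any trajectory", {
  cfg <- tiny_sim_config(mastery_gain = 30, failure_loss = 40)
  co <- generate_cohort(10, cfg, seed = 21)
  for (i in 1:10) {
    res <- simulate_user_weeks(co[i, ], weeks = 10, seed = 600 + i, config = cfg)
    expect_true(all(res$goals$self_efficacy >= 0 & res$goals$self_efficacy <= 100))
  }
})

test_that("an overshooting ladder with efficacy loss attenuates the late-study change", {
  # goals climb 1500/week with no confidence brake while ability tops
  # out near 1200 extra steps; clear failures erode self-efficacy, so
  # weeks 23-24 show no more gain than weeks 5-6
  cfg <- tiny_sim_config(
    mastery_gain = 0, failure_loss = 12, responsiveness = 1200,
    self_efficacy_mean = 80, self_efficacy_sd = 5
  )
  eng <- goal_config(increment = 1500, confidence_band = c(0, 100))
  co <- generate_cohort(60, cfg, seed = 14)
  trial <- run_trial(co, eng, seed = 15, weeks = 24, config = cfg)
  res <- evaluate_trial(trial, outcomes = "steps")
  d1 <- res$median_change[res$contrast == "P0b_to_P1b"]
  d2 <- res$median_change[res$contrast == "P0b_to_P2b"]
  expect_lte(d2, d1)
  expect_gt(d1, 0) # the engine still helps early on
})
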