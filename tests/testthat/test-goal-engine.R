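test_that("week-1 suggestions round the baseline, add one increment, and respect cap and floor", {
  expect_equal(suggest_week1_goal(10020), 10500)
  expect_equal(suggest_week1_goal(14800), 15000)
  expect_equal(suggest_week1_goal(900), 2000)
  expect_error(suggest_week1_goal(0), "positive")
})

test_that("weekly ladder raises on >=4 achieved days, holds on 2-3, lowers on <=1, clamps", {
  cfg <- goal_config()
  st <- goal_state(1, 10500, config = cfg)
  expect_equal(suggest_next_goal(st, week_performance(11000, 5, 10500), cfg), 11000)
  expect_equal(suggest_next_goal(st, week_performance(9000, 2, 10500), cfg), 10500)
  expect_equal(suggest_next_goal(st, week_performance(9000, 3, 10500), cfg), 10500)
  expect_equal(suggest_next_goal(st, week_performance(8000, 1, 10500), cfg), 10000)
  top <- goal_state(9, 15000, config = cfg)
  expect_equal(suggest_next_goal(top, week_performance(16000, 7, 15000), cfg), 15000)
  low <- goal_state(3, 2000, config = cfg)
  expect_equal(suggest_next_goal(low, week_performance(1000, 0, 2000), cfg), 2000)
  expect_error(suggest_next_goal(st, week_performance(9000, 2, 9999), cfg), "match")
})

test_that("confidence verdicts partition [0,100] with inclusive 70/90 boundaries", {
  expect_equal(assess_confidence(75), "appropriate")
  expect_equal(assess_confidence(70), "appropriate")
  expect_equal(assess_confidence(90), "appropriate")
  expect_equal(assess_confidence(100), "too_high")
  expect_equal(assess_confidence(69.99), "too_low")
  expect_error(assess_confidence(101), "0, 100")
  verdicts <- vapply(0:100, assess_confidence, character(1))
  expect_true(all(verdicts[0:69 + 1] == "too_low"))
  expect_true(all(verdicts[70:90 + 1] == "appropriate"))
  expect_true(all(verdicts[91:100 + 1] == "too_high"))
})

test_that("adjustment moves one increment toward the band and finalization honors overrides", {
  expect_equal(adjust_goal(10500, "too_high"), 11000)
  expect_equal(adjust_goal(10500, "appropriate"), 10500)
  expect_equal(adjust_goal(2000, "too_low"), 2000)
  st <- finalize_goal(10500, 1)
  expect_equal(st$goal, 10500)
  expect_equal(st$source, "suggested")
  st2 <- finalize_goal(10500, 1, user_override = 9000)
  expect_equal(st2$goal, 9000)
  expect_equal(st2$source, "self_set")
  expect_error(finalize_goal(10500, 1, user_override = 16000), "cap")
})

test_that("any achievement history keeps goals inside [floor, 15000]", {
  cfg <- goal_config()
  set.seed(42)
  for (rep in 1:50) {
    st <- goal_state(1, suggest_week1_goal(runif(1, 500, 20000) |> max(1), cfg), config = cfg)
    for (w in 2:30) {
      d <- sample(0:7, 1)
      g <- suggest_next_goal(st, week_performance(runif(1, 0, 20000), d, st$goal), cfg)
      expect_gte(g, cfg$floor)
      expect_lte(g, cfg$max_goal)
      st <- goal_state(w, g, days_achieved_prev_week = d, config = cfg)
    }
  }
})

test_that("perpetual achievement yields a non-decreasing ladder that reaches the cap", {
  cfg <- goal_config()
  g <- suggest_week1_goal(10020, cfg)
  goals <- g
  weeks_needed <- ceiling((cfg$max_goal - g) / cfg$increment)
  for (w in 2:(weeks_needed + 2)) {
    st <- goal_state(w - 1, g, config = cfg)
    g <- suggest_next_goal(st, week_performance(g + 1000, 7, g), cfg)
    goals <- c(goals, g)
  }
  expect_true(all(diff(goals) >= 0))
  expect_equal(max(goals), 15000)
  expect_equal(goals[weeks_needed + 1], 15000) # cap reached within the bound
})
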