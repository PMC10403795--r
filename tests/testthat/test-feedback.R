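catlg <- default_message_catalog()

test_that("daily feedback picks achieved messages at or above the goal, deterministically", {
  id <- daily_goal_feedback(10600, 10500, catlg, rng_seed = 7)
  expect_match(id, "^ach_")
  expect_match(daily_goal_feedback(10500, 10500, catlg, rng_seed = 7), "^ach_") # boundary counts
  expect_match(daily_goal_feedback(10499, 10500, catlg, rng_seed = 7), "^miss_")
  expect_identical(
    daily_goal_feedback(10600, 10500, catlg, rng_seed = 7),
    daily_goal_feedback(10600, 10500, catlg, rng_seed = 7)
  )
})

test_that("advice links only to never/rarely items, with a fallback when none exist", {
  one_low <- make_behavior(4, shopping_1 = 0)
  expect_equal(select_behavior_advice(one_low, catlg, 1), "adv_shopping_1")
  all_high <- make_behavior(4)
  expect_equal(select_behavior_advice(all_high, catlg, 1), "adv_fallback")
  # fuzz: chosen advice always maps to an item scored 0-1
  set.seed(9)
  for (i in 1:25) {
    resp <- behavior_response(stats::setNames(sample(0:4, 32, TRUE), essmbpa_items()))
    id <- select_behavior_advice(resp, catlg, rng_seed = i)
    if (id != "adv_fallback") {
      item <- catlg$linked_item[catlg$id == id]
      expect_lte(unclass(resp)[[item]], 1)
    }
  }
})

test_that("praise links only to often/always items, mirroring advice", {
  one_high <- make_behavior(0, exertion_2 = 3)
  expect_equal(select_behavior_praise(one_high, catlg, 1), "pra_exertion_2")
  expect_equal(select_behavior_praise(make_behavior(0), catlg, 1), "pra_fallback")
  set.seed(10)
  for (i in 1:25) {
    resp <- behavior_response(stats::setNames(sample(0:4, 32, TRUE), essmbpa_items()))
    id <- select_behavior_praise(resp, catlg, rng_seed = i)
    if (id != "pra_fallback") {
      item <- catlg$linked_item[catlg$id == id]
      expect_gte(unclass(resp)[[item]], 3)
    }
  }
})

test_that("selection is uniform over eligible entries", {
  # 5 never-scored items; 1e4 seeded draws should cover each ~20%
  resp <- make_behavior(4,
    shopping_1 = 0, household_1 = 0, exertion_1 = 0,
    commuting_1 = 0, self_monitoring_1 = 0
  )
  draws <- vapply(1:10000, function(i) select_behavior_advice(resp, catlg, rng_seed = i),
    character(1)
  )
  freq <- table(draws) / length(draws)
  expect_equal(length(freq), 5)
  expect_true(all(abs(freq - 0.2) < 0.02))
})

test_that("the immediately preceding advice is not repeated when avoidable", {
  resp <- make_behavior(4, shopping_1 = 0, household_1 = 0)
  for (i in 1:20) {
    expect_false(select_behavior_advice(resp, catlg, i, prev_id = "adv_shopping_1") ==
      "adv_shopping_1")
  }
  # single eligible entry: repetition unavoidable
  solo <- make_behavior(4, shopping_1 = 0)
  expect_equal(select_behavior_advice(solo, catlg, 1, prev_id = "adv_shopping_1"), "adv_shopping_1")
})

test_that("every fixture catalog entry is reachable by some input", {
  shipped <- load_message_catalog(system.file("extdata", "catalog.json", package = "stepcoach"))
  reached <- character(0)
  for (i in 1:400) { # daily kinds: cycle seeds
    reached <- union(reached, daily_goal_feedback(1, 0, shipped, i))
    reached <- union(reached, daily_goal_feedback(0, 1, shipped, i))
  }
  for (item in essmbpa_items()) {
    reached <- c(
      reached,
      select_behavior_advice(do.call(make_behavior, c(list(4), stats::setNames(list(0), item))), shipped, 1),
      select_behavior_praise(do.call(make_behavior, c(list(0), stats::setNames(list(4), item))), shipped, 1)
    )
  }
  reached <- c(
    reached,
    select_behavior_advice(make_behavior(4), shipped, 1),
    select_behavior_praise(make_behavior(0), shipped, 1)
  )
  st <- goal_state(2, 10500)
  this_w <- summarize_period(
    make_records(rep(12000, 7), sbp_m = 140, dbp_m = 95, sbp_n = 130, dbp_n = 85,
      weight_kg = 70, glucose_mgdl = 100, kcal_activity = 400),
    study_period("w", 1, 7)
  )
  for (delta in c(-1, 0, 1)) {
    prev_w <- summarize_period(
      make_records(rep(12000 - 500 * delta, 7),
        sbp_m = 140 - 5 * delta, dbp_m = 95 - 5 * delta,
        sbp_n = 130 - 5 * delta, dbp_n = 85 - 5 * delta,
        weight_kg = 70 - delta, glucose_mgdl = 100 - 5 * delta,
        kcal_activity = 400 - 50 * delta
      ),
      study_period("w", 1, 7)
    )
    fb <- compose_weekly_feedback(this_w, prev_w, st, 5, shipped)
    reached <- union(reached, unname(fb$change_messages))
  }
  expect_setequal(shipped$id, reached)
})

test_that("weekly feedback reports means and classifies changes with a tolerance", {
  st <- goal_state(2, 10500)
  wk <- function(steps, weight, sbp) {
    summarize_period(
      make_records(rep(steps, 7), weight_kg = weight, sbp_m = sbp),
      study_period("w", 1, 7)
    )
  }
  fb <- compose_weekly_feedback(wk(11000, 67.0, 130), wk(10000, 68.0, 130.5), st, 4, catlg)
  expect_equal(unname(fb$change_messages["weight_kg"]), "chg_weight_kg_down")
  expect_equal(unname(fb$change_messages["steps"]), "chg_steps_up")
  expect_equal(unname(fb$change_messages["sbp_m"]), "chg_sbp_m_flat") # |-0.5| < 1 mm Hg
  expect_equal(fb$mean_steps, 11000)
  expect_equal(fb$days_achieved, 4L)
  # first week of use: no trend messages, means still present
  fb1 <- compose_weekly_feedback(wk(11000, 67.0, 130), NULL, st, 4, catlg)
  expect_length(fb1$change_messages, 0)
  expect_equal(fb1$means[["weight_kg"]], 67.0)
})
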