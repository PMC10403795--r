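test_that("CSV loading parses rows, keeps missing cells missing, rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,date,steps,worn,recording_failure,sbp_m,dbp_m,sbp_n,dbp_n,weight_kg,glucose_mgdl,kcal_activity",
    "p1,2024-01-01,9500,true,false,132.5,88,126,80,66.2,,310",
    "p1,2024-01-02,,true,false,,,,,,,",
    "p1,2024-01-03,10400,,false,130,86,,,66.0,95,330"
  ), path)
  rec <- load_daily_records(path)
  expect_equal(nrow(rec), 3)
  expect_true(is.na(rec$steps[2]))      # empty cell is missing, not zero
  expect_true(is.na(rec$worn[3]))
  expect_equal(rec$steps[1], 9500)
  expect_equal(rec$sbp_m[1], 132.5)

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "participant_id,date,steps",
    "p1,2024-01-01,9500",
    "p1,2024-01-01,9600"
  ), dup)
  expect_error(load_daily_records(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant_id,date,steps", "p1,2024-01-01,lots"), bad)
  expect_error(load_daily_records(bad), "line 2")
})

test_that("step cleaning drops non-wear and sub-100 days, keeps the 100 boundary, is idempotent", {
  rec <- make_records(c(50, 100, 9000, 8000, 7000),
    worn = c(NA, TRUE, FALSE, NA, TRUE)
  )
  out <- clean_step_series(rec)
  expect_equal(out$steps, c(100, 8000, 7000)) # 50 < 100 out; worn=FALSE out; NA worn kept
  expect_identical(clean_step_series(out), out)
  # output is always a subset of input with valid days only
  expect_true(all(out$date %in% rec$date))
  expect_true(all(out$steps >= 100))
})

test_that("period windows use study-day indexing with P0b = days 1-14", {
  rec <- make_records(rep(10000, 200))
  p <- standard_periods()
  expect_equal(nrow(window_period(rec, p$P0b)), 14)
  expect_equal(nrow(window_period(rec, p$P1b)), 14)
  expect_equal(p$P1b$start_day, 48) # week 5 starts after 14 baseline + 5 gap + 4 weeks
  expect_equal(p$P2b$end_day, 14 + 5 + 24 * 7)
  expect_equal(nrow(window_period(rec, intervention_weeks(5))), 7)
  empty <- rec[0, ]
  expect_equal(nrow(window_period(empty, p$P0b)), 0)
})

test_that("adherence excludes recording-failure days from the denominator", {
  p0b <- standard_periods()$P0b
  steps <- c(rep(10000, 13), NA)
  rec <- make_records(steps, recording_failure = c(rep(FALSE, 13), TRUE))
  expect_equal(adherence_percentage(rec, p0b), 100)

  rec2 <- make_records(c(rep(10000, 7), rep(NA, 7)))
  expect_equal(adherence_percentage(rec2, p0b), 50)

  rec3 <- make_records(rep(NA_real_, 14), recording_failure = TRUE)
  expect_error(adherence_percentage(rec3, p0b), "recording failures")

  # monotone: recording an extra day never lowers adherence
  base <- c(rep(10000, 5), rep(NA, 9))
  a1 <- adherence_percentage(make_records(base), p0b)
  base[6] <- 10000
  a2 <- adherence_percentage(make_records(base), p0b)
  expect_gte(a2, a1)
  expect_true(a1 >= 0 && a2 <= 100)
})

test_that("reminders trigger after 3 consecutive unrecorded days", {
  start <- as.Date("2024-01-01")
  rec <- make_records(c(10000, 9000, NA, NA, NA), start = start)
  expect_true(reminder_due(rec, start + 5))
  rec2 <- make_records(c(10000, NA, NA, 9000), start = start)
  expect_false(reminder_due(rec2, start + 4))
  short <- make_records(c(NA, NA), start = start)
  expect_false(reminder_due(short, start + 2)) # under 3 days of history
})

test_that("period summaries average valid days only and leave absent parameters missing", {
  rec <- make_records(c(10000, 12000, NA, 50),
    sbp_m = c(130, NA, 128, NA),
    weight_kg = NA_real_
  )
  s <- summarize_period(rec, study_period("w", 1, 7))
  expect_equal(s$mean_steps, 11000) # 50-step day cleaned away, NA skipped
  expect_equal(s$n_steps, 2)
  expect_equal(s$mean_sbp_m, 129)
  expect_equal(s$n_sbp_m, 2)
  expect_true(is.na(s$mean_weight_kg))
  # constant series mean equals the constant
  s2 <- summarize_period(make_records(rep(8000, 14)), standard_periods()$P0b)
  expect_equal(s2$mean_steps, 8000)
})
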