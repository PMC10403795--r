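#' Replay the coaching engine over recorded data
#'
#' Given a participant's daily records and their weekly interaction log
#' (reported confidence and optional self-set goal), the coach replays
#' the weekly goal sessions and the daily/weekly feedback the engine
#' would have produced, yielding a deterministic transcript under a
#' fixed seed.  Weeks are consecutive 7-day blocks starting at
#' intervention day 1; a trailing partial week is skipped with a
#' warning.
#'
#' @param records one participant's `daily_records` covering the
#'   baseline device period and the intervention.
#' @param interactions data frame with `week` and optional `confidence`
#'   (percent) and `override` (self-set goal) columns; missing weeks run
#'   with no confidence check and no override.
#' @param behavior optional [behavior_response()] driving advice/praise
#'   selection; without it, fallback messages are used.
#' @param engine_config a [goal_config()].
#' @param catalog a [message_catalog()].
#' @param seed integer seed for message selection.
#' @param rule step [cleaning_rule()].
#' @param start_date calendar date of study day 1.
#' @param gap_days non-study days between baseline and intervention.
#' @return list with `transcript` (one row per emitted message: week,
#'   date, kind, message_id) and `goal_trace` (per-week goal, source,
#'   verdict, days achieved, routing).
#' @export
coach_replay <- function(records, interactions = NULL, behavior = NULL,
                         engine_config = goal_config(),
                         catalog = default_message_catalog(),
                         seed = 1, rule = cleaning_rule(),
                         start_date = NULL, gap_days = 5) {
  if (nrow(records) == 0) stop_input("no records to coach over")
  if (is.null(start_date)) start_date <- min(records$date)
  start_date <- as.Date(start_date)
  day_index <- as.integer(records$date - start_date) + 1L

  p0b <- standard_periods(gap_days)$P0b
  base <- clean_step_series(window_period(records, p0b, start_date), rule)
  if (nrow(base) == 0) stop_input("no valid baseline step days; cannot suggest a goal")
  baseline_mean <- mean(base$steps)

  last_day <- max(day_index)
  n_weeks <- (last_day - 14 - gap_days) %/% 7
  if (n_weeks < 1) stop_input("records do not cover a full intervention week")
  if ((last_day - 14 - gap_days) %% 7 != 0) {
    warning("records end mid-week; final partial week skipped", call. = FALSE)
  }

  transcript <- list()
  trace <- list()
  prev_state <- NULL
  prev_perf <- NULL
  prev_daily_id <- NULL
  prev_behavior_id <- NULL
  emit <- function(week, date, kind, id) {
    transcript[[length(transcript) + 1]] <<- data.frame(
      week = week, date = as.character(date), kind = kind, message_id = id,
      stringsAsFactors = FALSE
    )
  }

  for (w in seq_len(n_weeks)) {
    suggestion <- if (w == 1) {
      suggest_week1_goal(baseline_mean, engine_config)
    } else {
      suggest_next_goal(prev_state, prev_perf, engine_config)
    }
    inter <- if (!is.null(interactions)) interactions[interactions$week == w, , drop = FALSE] else NULL
    conf <- if (!is.null(inter) && nrow(inter) && !is.null(inter$confidence)) inter$confidence[1] else NA
    override <- if (!is.null(inter) && nrow(inter) && !is.null(inter$override)) inter$override[1] else NA
    proposal <- suggestion
    adjusted <- FALSE
    verdict <- NA_character_
    if (!is.na(conf)) {
      verdict <- assess_confidence(conf, engine_config)
      if (verdict != "appropriate") {
        proposal <- adjust_goal(proposal, verdict, engine_config)
        adjusted <- TRUE
      }
    }
    state <- finalize_goal(proposal, w,
      user_override = if (is.na(override)) NULL else override,
      adjusted = adjusted,
      confidence = if (is.na(conf)) NA_real_ else conf,
      config = engine_config
    )

    week_start <- 14 + gap_days + (w - 1) * 7 + 1
    wrec <- records[day_index >= week_start & day_index < week_start + 7, , drop = FALSE]
    wvalid <- clean_step_series(wrec, rule)
    for (i in seq_len(nrow(wvalid))) {
      steps_i <- wvalid$steps[i]
      sid <- derive_seed(seed, week_start * 10 + i)
      id <- daily_goal_feedback(steps_i, state$goal, catalog, sid, prev_daily_id)
      emit(w, wvalid$date[i], if (steps_i >= state$goal) "daily_achieved" else "daily_missed", id)
      prev_daily_id <- id
      if (!is.null(behavior)) {
        bid <- if (steps_i >= state$goal) {
          select_behavior_praise(behavior, catalog, derive_seed(seed, week_start * 100 + i), prev_behavior_id)
        } else {
          select_behavior_advice(behavior, catalog, derive_seed(seed, week_start * 100 + i), prev_behavior_id)
        }
        emit(w, wvalid$date[i], if (steps_i >= state$goal) "behavior_praise" else "behavior_advice", bid)
        prev_behavior_id <- bid
      }
    }

    days_achieved <- sum(wvalid$steps >= state$goal)
    mean_steps <- if (nrow(wvalid)) mean(wvalid$steps) else 0
    perf <- week_performance(mean_steps, days_achieved, state$goal)
    route <- route_weekly_session(perf, engine_config$raise_threshold_days)

    week_period <- study_period(sprintf("week %d", w), week_start, week_start + 6)
    this_sum <- summarize_period(records, week_period, rule, start_date)
    prev_sum <- if (w > 1) {
      summarize_period(
        records,
        study_period("prev", week_start - 7, week_start - 1), rule, start_date
      )
    } else {
      NULL
    }
    weekly <- compose_weekly_feedback(this_sum, prev_sum, state, days_achieved, catalog)
    for (mid in weekly$change_messages) {
      emit(w, format(start_date + week_start + 5), "weekly_change", mid)
    }

    trace[[w]] <- data.frame(
      week = w, suggested = suggestion, goal = state$goal, source = state$source,
      confidence = state$confidence, verdict = verdict,
      days_achieved = days_achieved, mean_steps = mean_steps, route = route,
      stringsAsFactors = FALSE
    )
    prev_state <- state
    prev_perf <- perf
  }

  list(
    transcript = do.call(rbind, transcript),
    goal_trace = do.call(rbind, trace),
    baseline_mean = baseline_mean
  )
}
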