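#' Weekly step-goal engine
#'
#' The engine proposes a daily step goal once a week.  Week 1 starts from
#' the participant's baseline mean; later weeks move the previous goal up
#' or down one increment according to how many days of the previous week
#' the goal was achieved.  The participant then reports their confidence
#' (0-100%) of achieving the goal on more than half the days of the
#' coming week; confidence between 70% and 90% (inclusive) marks the goal
#' as appropriate — challenging yet attainable — and anything outside the
#' band triggers a suggested adjustment before the goal is finalized.
#' Goals are always clamped to `[floor, max_goal]`; both the suggestion
#' cap and the user-input cap are 15,000 steps/day.
#'
#' @name goal-engine
NULL

#' Goal-engine configuration
#'
#' @param max_goal hard cap on suggested and user-entered goals
#'   (steps/day).
#' @param confidence_band inclusive `[low, high]` percent band in which a
#'   goal is judged appropriate.
#' @param increment ladder step size (steps/day).
#' @param rounding baseline means are rounded to this multiple before the
#'   first increment is added.
#' @param floor minimum goal (steps/day).
#' @param raise_threshold_days achieved days/week at or above which the
#'   goal is raised.
#' @param hold_range_days achieved days/week range (inclusive) holding the
#'   goal; fewer lowers it.
#' @export
goal_config <- function(max_goal = 15000, confidence_band = c(70, 90),
                        increment = 500, rounding = 100, floor = 2000,
                        raise_threshold_days = 4, hold_range_days = c(2, 3)) {
  if (floor >= max_goal) stop_input("goal floor must be below max_goal")
  if (increment <= 0) stop_input("increment must be positive")
  band <- as.numeric(confidence_band)
  if (length(band) != 2 || band[1] > band[2] || band[1] < 0 || band[2] > 100) {
    stop_input("confidence_band must be [low, high] within [0, 100]")
  }
  structure(
    list(
      max_goal = max_goal, confidence_band = band, increment = increment,
      rounding = rounding, floor = floor,
      raise_threshold_days = raise_threshold_days,
      hold_range_days = as.numeric(hold_range_days)
    ),
    class = "goal_config"
  )
}

#' Load a goal-engine configuration from JSON
#' @param path JSON file whose fields override [goal_config()] defaults.
#' @export
load_goal_config <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(goal_config, spec[intersect(names(spec), names(formals(goal_config)))])
}

#' Goal state for one intervention week
#'
#' @param week_index intervention week (1-based).
#' @param goal finalized goal (steps/day).
#' @param source how the goal was arrived at: system-`"suggested"`,
#'   `"self_set"` by the user, or `"adjusted"` after a confidence check.
#' @param confidence reported confidence (percent), if any.
#' @param days_achieved_prev_week achieved days feeding this week's
#'   suggestion, if any.
#' @param config a [goal_config()] used for range validation.
#' @export
goal_state <- function(week_index, goal, source = c("suggested", "self_set", "adjusted"),
                       confidence = NA_real_, days_achieved_prev_week = NA_integer_,
                       config = goal_config()) {
  source <- match.arg(source)
  if (week_index < 1) stop_input("week_index must be >= 1")
  if (goal < config$floor || goal > config$max_goal) {
    stop_input("goal %s outside [%s, %s]", goal, config$floor, config$max_goal)
  }
  if (!is.na(confidence) && (confidence < 0 || confidence > 100)) {
    stop_input("confidence must lie in [0, 100]")
  }
  structure(
    list(
      week_index = as.integer(week_index), goal = goal, source = source,
      confidence = confidence,
      days_achieved_prev_week = days_achieved_prev_week
    ),
    class = "goal_state"
  )
}

#' Suggest the first-week goal from baseline steps
#'
#' The baseline mean is rounded to the nearest `rounding` multiple and one
#' increment is added, capped at `max_goal` and floored at `floor`.
#'
#' @param baseline_mean_steps mean steps/day over the cleaned baseline
#'   period.
#' @param config a [goal_config()].
#' @return suggested goal (steps/day).
#' @export
suggest_week1_goal <- function(baseline_mean_steps, config = goal_config()) {
  if (!is_scalar_number(baseline_mean_steps) || baseline_mean_steps <= 0) {
    stop_input("baseline mean steps must be a positive number")
  }
  g <- round_to(baseline_mean_steps, config$rounding) + config$increment
  clamp(g, config$floor, config$max_goal)
}

#' Suggest the next week's goal from last week's achievement
#'
#' Achieving the goal on at least `raise_threshold_days` days raises the
#' goal one increment; an achieved-day count inside `hold_range_days`
#' holds it; fewer lowers it one increment.  The result is clamped to
#' `[floor, max_goal]`.
#'
#' @param prev a [goal_state()] for the completed week.
#' @param perf a [week_performance()] for the same week.
#' @param config a [goal_config()].
#' @export
suggest_next_goal <- function(prev, perf, config = goal_config()) {
  stopifnot(inherits(prev, "goal_state"), inherits(perf, "week_performance"))
  if (!isTRUE(all.equal(perf$goal, prev$goal))) {
    stop_input("performance goal (%s) does not match the week's goal state (%s)",
      perf$goal, prev$goal)
  }
  d <- perf$days_achieved
  g <- if (d >= config$raise_threshold_days) {
    prev$goal + config$increment
  } else if (d >= config$hold_range_days[1] && d <= config$hold_range_days[2]) {
    prev$goal
  } else {
    prev$goal - config$increment
  }
  clamp(g, config$floor, config$max_goal)
}

#' One week's performance against its goal
#'
#' @param mean_steps mean steps/day over valid days of the week.
#' @param days_achieved days (0-7) on which steps reached the goal.
#' @param goal the goal in force that week.
#' @export
week_performance <- function(mean_steps, days_achieved, goal) {
  if (days_achieved < 0 || days_achieved > 7) stop_input("days_achieved must be 0-7")
  structure(
    list(mean_steps = mean_steps, days_achieved = as.integer(days_achieved), goal = goal),
    class = "week_performance"
  )
}

#' Judge reported confidence against the appropriateness band
#'
#' @param confidence percent in `[0, 100]`.
#' @param config a [goal_config()].
#' @return `"appropriate"` inside the (inclusive) band, `"too_low"` below
#'   it, `"too_high"` above it.
#' @export
assess_confidence <- function(confidence, config = goal_config()) {
  if (!is_scalar_number(confidence) || confidence < 0 || confidence > 100) {
    stop_input("confidence must be a number in [0, 100]")
  }
  band <- config$confidence_band
  if (confidence < band[1]) "too_low"
  else if (confidence > band[2]) "too_high"
  else "appropriate"
}

#' Propose an adjusted goal after a confidence verdict
#'
#' Over-confidence (`too_high`) means the goal is too easy, so one
#' increment is added; under-confidence removes one.  An appropriate
#' verdict leaves the goal unchanged.  Results are clamped.
#'
#' @param goal current proposal (steps/day).
#' @param verdict a value returned by [assess_confidence()].
#' @param config a [goal_config()].
#' @export
adjust_goal <- function(goal, verdict = c("appropriate", "too_low", "too_high"),
                        config = goal_config()) {
  verdict <- match.arg(verdict)
  g <- switch(verdict,
    appropriate = goal,
    too_low = goal - config$increment,
    too_high = goal + config$increment
  )
  clamp(g, config$floor, config$max_goal)
}

#' Finalize the week's goal
#'
#' The user may override the proposal with a self-set goal; overrides
#' above the input cap are rejected, mirroring the app's entry limit.
#'
#' @param proposal system proposal (steps/day).
#' @param week_index intervention week.
#' @param user_override self-set goal, or `NULL` to accept the proposal.
#' @param adjusted whether the proposal came out of [adjust_goal()].
#' @param confidence last reported confidence.
#' @param config a [goal_config()].
#' @return a [goal_state()].
#' @export
finalize_goal <- function(proposal, week_index, user_override = NULL,
                          adjusted = FALSE, confidence = NA_real_,
                          config = goal_config()) {
  if (!is.null(user_override)) {
    if (user_override > config$max_goal) {
      stop_input("self-set goal %s exceeds the input cap of %s steps/day",
        user_override, config$max_goal)
    }
    goal <- clamp(user_override, config$floor, config$max_goal)
    source <- "self_set"
  } else {
    goal <- clamp(proposal, config$floor, config$max_goal)
    source <- if (adjusted) "adjusted" else "suggested"
  }
  goal_state(week_index, goal, source, confidence = confidence, config = config)
}
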