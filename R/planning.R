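#' Weekly action planning and barrier problem-solving
#'
#' After the week's goal is set, the session either reviews/builds an
#' action plan or — depending on last week's performance — elicits
#' barriers and solutions instead: a clearly successful week routes to
#' *future* barriers (relapse prevention: even when the goal is reached,
#' thinking ahead to obstacles sustains the behavior), a clearly failed
#' week routes to *current* barriers, and anything in between reviews the
#' action plan.
#'
#' @name planning
NULL

#' The 12-action general information list
#'
#' @return an `action_catalog`: data frame of 12 predefined everyday
#'   actions for increasing step count, plus support for free-text
#'   entries at plan-building time.
#' @export
default_action_catalog <- function() {
  action_catalog(data.frame(
    id = 1:12,
    text = c(
      "Get off the bus or train one stop early and walk",
      "Take the stairs instead of the elevator or escalator",
      "Walk to a shop a little farther away",
      "Take a 10-minute walk during your lunch break",
      "Park at the far end of the parking area",
      "Walk while talking on the phone",
      "Stand up and walk around once every hour at work",
      "Walk with a family member, friend, or pet after dinner",
      "Choose a walking route with pleasant scenery",
      "Do errands on foot instead of online or by car",
      "Walk briskly for 10 minutes in the morning",
      "Use part of your commute as a walking course"
    ),
    stringsAsFactors = FALSE
  ))
}

#' @rdname default_action_catalog
#' @param entries data frame with `id` and `text` columns.
#' @export
action_catalog <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!all(c("id", "text") %in% names(entries))) {
    stop_input("action catalog needs 'id' and 'text' columns")
  }
  if (anyDuplicated(entries$id)) stop_input("action ids must be unique")
  structure(entries, class = c("action_catalog", "data.frame"))
}

#' Load an action catalog from JSON
#' @param path JSON file with an `actions` array of `{id, text}`.
#' @export
load_action_catalog <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  action_catalog(if (is.data.frame(spec)) spec else spec$actions)
}

#' Barrier and solution lists
#'
#' Separate lists of common *current* and *future* barriers to walking,
#' each mapped to at least one concrete solution.
#'
#' @param barriers data frame with `id`, `when` (`"current"` or
#'   `"future"`) and `text`.
#' @param solutions data frame with `barrier_id`, `solution_id`, `text`.
#' @export
barrier_catalog <- function(barriers, solutions) {
  barriers <- as.data.frame(barriers, stringsAsFactors = FALSE)
  solutions <- as.data.frame(solutions, stringsAsFactors = FALSE)
  if (!all(barriers$when %in% c("current", "future"))) {
    stop_input("barrier 'when' must be 'current' or 'future'")
  }
  if (anyDuplicated(barriers$id)) stop_input("barrier ids must be unique")
  missing_sol <- setdiff(barriers$id, solutions$barrier_id)
  if (length(missing_sol)) {
    stop_input("every barrier needs at least one solution; missing: %s",
      paste(missing_sol, collapse = ", "))
  }
  structure(list(barriers = barriers, solutions = solutions),
    class = "barrier_catalog"
  )
}

#' Built-in fixture barrier catalog
#'
#' Eight current and six future barriers spanning the common categories
#' (weather, workload, fatigue, time pressure, motivation, pain, company,
#' holidays), each with 2-4 solutions.
#' @export
default_barrier_catalog <- function() {
  barriers <- data.frame(
    id = c(paste0("c", 1:8), paste0("f", 1:6)),
    when = c(rep("current", 8), rep("future", 6)),
    text = c(
      "Bad weather (rain or snow)",
      "Too busy at work",
      "Feeling tired after work",
      "No time in the daily schedule",
      "Low motivation to walk",
      "Foot, knee, or back pain",
      "No one to walk with",
      "Walking feels boring",
      "Year-end and New Year holidays will disrupt the routine",
      "Winter cold will make walking unpleasant",
      "A coming busy season at work",
      "Travel or business trips",
      "Possible illness or injury",
      "Losing interest once the novelty wears off"
    ),
    stringsAsFactors = FALSE
  )
  sol <- function(b, ...) {
    txt <- c(...)
    data.frame(
      barrier_id = b, solution_id = paste0(b, "_s", seq_along(txt)),
      text = txt, stringsAsFactors = FALSE
    )
  }
  solutions <- rbind(
    sol("c1", "Walk indoors (shopping mall, station concourse)", "Keep an umbrella and walking shoes at work", "Use a stair circuit at home"),
    sol("c2", "Split walking into several 5-minute bouts", "Walk during phone meetings"),
    sol("c3", "Walk right after leaving work, before sitting down", "Choose a shorter but brisker route", "Go to bed earlier to recover"),
    sol("c4", "Attach walking to an existing habit such as commuting", "Get off one stop early on the way home"),
    sol("c5", "Set a smaller goal for a few days and rebuild momentum", "Listen to music or podcasts while walking", "Reward yourself after a walking streak"),
    sol("c6", "Ask a professional about footwear and insoles", "Switch to shorter, more frequent walks", "Warm up and stretch before walking"),
    sol("c7", "Join a local walking group", "Invite a colleague to a lunchtime walk"),
    sol("c8", "Change the route or direction every week", "Track scenery photos along the walk"),
    sol("f1", "Plan family walks to shrines or sales events", "Keep the morning walk fixed even on holidays"),
    sol("f2", "Prepare warm clothing in advance", "Shift walks to the warmest part of the day", "Walk indoors on the coldest days"),
    sol("f3", "Agree with yourself on a minimum daily walk", "Schedule walks in the calendar like meetings"),
    sol("f4", "Pack walking shoes when traveling", "Explore the destination on foot"),
    sol("f5", "Have a low-intensity fallback routine", "Resume gradually with reduced goals"),
    sol("f6", "Review progress graphs monthly", "Set a seasonal event goal such as a charity walk")
  )
  barrier_catalog(barriers, solutions)
}

#' Load a barrier catalog from JSON
#' @param path JSON file with `barriers` and `solutions` arrays.
#' @export
load_barrier_catalog <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  barrier_catalog(spec$barriers, spec$solutions)
}

#' Route the weekly session
#'
#' A week with at least `raise_threshold` achieved days *and* a mean at
#' or above the goal routes to future-barrier identification; at most
#' `fail_days` achieved days *or* a mean below `fail_fraction` of the
#' goal routes to current barriers; otherwise the action plan is
#' reviewed.
#'
#' @param perf a [week_performance()].
#' @param raise_threshold achieved-days cutoff for a successful week.
#' @param fail_days achieved-days cutoff for a failed week.
#' @param fail_fraction fraction of goal below which the week counts as
#'   failed.
#' @return one of `"future_barriers"`, `"current_barriers"`,
#'   `"review_plan"`.
#' @export
route_weekly_session <- function(perf, raise_threshold = 4, fail_days = 1,
                                 fail_fraction = 0.8) {
  stopifnot(inherits(perf, "week_performance"))
  if (perf$days_achieved >= raise_threshold && perf$mean_steps >= perf$goal) {
    "future_barriers"
  } else if (perf$days_achieved <= fail_days || perf$mean_steps < fail_fraction * perf$goal) {
    "current_barriers"
  } else {
    "review_plan"
  }
}

#' Build a weekly action plan
#'
#' Users choose any number of actions from the 12-action list and may add
#' free-text actions; an empty plan is allowed.
#'
#' @param week_index intervention week.
#' @param chosen_ids ids from the action catalog.
#' @param free_texts character vector of user-entered actions.
#' @param catalog an [action_catalog()].
#' @return an `action_plan` list.
#' @export
build_action_plan <- function(week_index, chosen_ids = integer(0),
                              free_texts = character(0),
                              catalog = default_action_catalog()) {
  unknown <- setdiff(chosen_ids, catalog$id)
  if (length(unknown)) {
    stop_input("unknown action id(s): %s", paste(unknown, collapse = ", "))
  }
  structure(
    list(
      week_index = as.integer(week_index),
      chosen_ids = chosen_ids,
      free_texts = as.character(free_texts)
    ),
    class = "action_plan"
  )
}

#' Pair selected barriers with their solution lists
#'
#' @param barrier_ids ids from the routed list.
#' @param catalog a [barrier_catalog()].
#' @param session `"current"` or `"future"`; ids from the other list are
#'   rejected to keep routing and elicitation consistent.
#' @return list of `(barrier_id, solution_ids)` pairs, order preserved.
#' @export
elicit_barrier_solutions <- function(barrier_ids, catalog = default_barrier_catalog(),
                                     session = c("current", "future")) {
  session <- match.arg(session)
  valid <- catalog$barriers$id[catalog$barriers$when == session]
  unknown <- setdiff(barrier_ids, valid)
  if (length(unknown)) {
    stop_input("barrier id(s) not in the %s-barrier list: %s", session,
      paste(unknown, collapse = ", "))
  }
  lapply(barrier_ids, function(b) {
    list(
      barrier_id = b,
      solution_ids = catalog$solutions$solution_id[catalog$solutions$barrier_id == b]
    )
  })
}
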