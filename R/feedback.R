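#' Positive-feedback message engine
#'
#' Messages live in a catalog of identified entries of five kinds:
#' `daily_achieved` and `daily_missed` (daily goal-achievement feedback),
#' `behavior_advice` (recommends a behavior the user never/rarely does,
#' shown on missed days), `behavior_praise` (recognizes a behavior the
#' user often/always does, shown on achieved days), and `weekly_change`
#' (per-parameter trend messages in the weekly summary).  Advice and
#' praise entries are each linked to exactly one of the 32 ES-SMBPA-2D
#' behavior items.  Selection among eligible entries is uniform under a
#' seeded generator and avoids repeating the immediately preceding
#' message when at least two entries are eligible, so a fixed seed yields
#' a byte-identical feedback transcript for a fixed input trajectory.
#'
#' @name feedback-engine
NULL

CATALOG_KINDS <- c(
  "daily_achieved", "daily_missed", "behavior_advice", "behavior_praise",
  "weekly_change"
)

#' Construct a validated message catalog
#'
#' @param entries data frame with columns `id`, `kind`, `text`, and
#'   optionally `linked_item` (ES-SMBPA-2D item id; required for advice
#'   and praise kinds), `parameter` and `direction` (required for
#'   `weekly_change` entries), `fallback` (logical; generic entries used
#'   when no behavior item is eligible).
#' @export
message_catalog <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  needed <- c("id", "kind", "text")
  if (!all(needed %in% names(entries))) {
    stop_input("catalog entries need columns %s", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(entries$id)) stop_input("catalog ids must be unique")
  if (!all(entries$kind %in% CATALOG_KINDS)) {
    stop_input("unknown catalog kind(s): %s",
      paste(setdiff(unique(entries$kind), CATALOG_KINDS), collapse = ", "))
  }
  if (is.null(entries$linked_item)) entries$linked_item <- NA_character_
  if (is.null(entries$fallback)) entries$fallback <- FALSE
  entries$fallback[is.na(entries$fallback)] <- FALSE
  if (is.null(entries$parameter)) entries$parameter <- NA_character_
  if (is.null(entries$direction)) entries$direction <- NA_character_
  behav <- entries$kind %in% c("behavior_advice", "behavior_praise") & !entries$fallback
  bad <- behav & !(entries$linked_item %in% essmbpa_items())
  if (any(bad)) {
    stop_input("advice/praise entries must link to one ES-SMBPA-2D item: %s",
      paste(entries$id[bad], collapse = ", "))
  }
  structure(entries, class = c("message_catalog", "data.frame"))
}

#' Load a message catalog from JSON
#' @param path JSON file with an `entries` array.
#' @export
load_message_catalog <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- if (is.data.frame(spec)) spec else spec$entries
  message_catalog(entries)
}

#' Built-in English fixture catalog
#'
#' One advice and one praise entry per ES-SMBPA-2D item, generic
#' fallbacks, three daily-achieved and three daily-missed variants, and
#' increased/decreased/stable weekly-change entries for each tracked
#' parameter.  Text is short placeholder English keyed to the behavior
#' item; wording is not part of the engine's contract.
#' @export
default_message_catalog <- function() {
  items <- essmbpa_items()
  rows <- list(
    data.frame(
      id = paste0("ach_", 1:3), kind = "daily_achieved",
      text = c(
        "Goal achieved - great work today!",
        "You hit today's step goal. Keep it up!",
        "Another goal met. Your consistency is paying off."
      ), stringsAsFactors = FALSE
    ),
    data.frame(
      id = paste0("miss_", 1:3), kind = "daily_missed",
      text = c(
        "Not quite there today - tomorrow is a fresh start.",
        "A short walk this evening could close the gap next time.",
        "Missed today's goal; small extra walks add up."
      ), stringsAsFactors = FALSE
    ),
    data.frame(
      id = paste0("adv_", items), kind = "behavior_advice",
      text = paste0("Try this: ", gsub("_", " ", items), "."),
      linked_item = items, stringsAsFactors = FALSE
    ),
    data.frame(
      id = paste0("pra_", items), kind = "behavior_praise",
      text = paste0("Nice habit: ", gsub("_", " ", items), " - keep doing it!"),
      linked_item = items, stringsAsFactors = FALSE
    ),
    data.frame(
      id = c("adv_fallback", "pra_fallback"),
      kind = c("behavior_advice", "behavior_praise"),
      text = c(
        "Every extra step counts - look for one more chance to walk today.",
        "You are keeping up many good activity habits - well done!"
      ),
      fallback = TRUE, stringsAsFactors = FALSE
    )
  )
  params <- c("steps", "kcal", "sbp_m", "dbp_m", "sbp_n", "dbp_n", "weight_kg", "glucose_mgdl")
  for (p in params) {
    rows[[length(rows) + 1]] <- data.frame(
      id = paste0("chg_", p, "_", c("up", "down", "flat")),
      kind = "weekly_change",
      text = paste0("Your weekly mean ", p, " ", c("increased", "decreased", "stayed stable"), "."),
      parameter = p,
      direction = c("increased", "decreased", "stable"),
      stringsAsFactors = FALSE
    )
  }
  all <- do.call(rbind, lapply(rows, function(r) {
    for (col in c("linked_item", "parameter", "direction")) {
      if (is.null(r[[col]])) r[[col]] <- NA_character_
    }
    if (is.null(r$fallback)) r$fallback <- FALSE
    r[c("id", "kind", "text", "linked_item", "parameter", "direction", "fallback")]
  }))
  message_catalog(all)
}

# uniform seeded choice among candidate ids, avoiding `prev_id` when at
# least two candidates exist
pick_message <- function(ids, rng_seed, prev_id = NULL) {
  if (length(ids) == 0) stop_input("no applicable catalog entry")
  if (!is.null(prev_id) && length(ids) >= 2) ids <- setdiff(ids, prev_id)
  if (length(ids) == 1) return(ids)
  with_seed(rng_seed, ids[sample.int(length(ids), 1)])
}

#' Daily goal-achievement feedback
#'
#' Meeting the goal exactly counts as achieved.
#'
#' @param steps today's (valid) step count.
#' @param goal the week's goal (steps/day).
#' @param catalog a [message_catalog()].
#' @param rng_seed integer seed making the choice reproducible.
#' @param prev_id id of the previous message of the same kind, never
#'   repeated when avoidable.
#' @return a message id.
#' @export
daily_goal_feedback <- function(steps, goal, catalog = default_message_catalog(),
                                rng_seed = 1, prev_id = NULL) {
  kind <- if (steps >= goal) "daily_achieved" else "daily_missed"
  pick_message(catalog$id[catalog$kind == kind], rng_seed, prev_id)
}

eligible_entries <- function(response, catalog, kind, score_test) {
  scores <- unclass(response)
  ok_items <- names(scores)[!is.na(scores) & score_test(scores)]
  sel <- catalog$kind == kind & !catalog$fallback & catalog$linked_item %in% ok_items
  catalog$id[sel]
}

#' Recommend a behavior the user never or rarely does
#'
#' Invoked when the day's goal was missed.  Eligible entries are advice
#' messages linked to items scored never/rarely (0-1 on the frequency
#' scale); with no eligible item a generic-encouragement fallback id is
#' returned.
#'
#' @inheritParams daily_goal_feedback
#' @param response a [behavior_response()].
#' @export
select_behavior_advice <- function(response, catalog = default_message_catalog(),
                                   rng_seed = 1, prev_id = NULL) {
  ids <- eligible_entries(response, catalog, "behavior_advice", function(s) s <= 1)
  if (length(ids) == 0) {
    fb <- catalog$id[catalog$kind == "behavior_advice" & catalog$fallback]
    if (length(fb) == 0) stop_input("catalog has no advice fallback entry")
    return(fb[1])
  }
  pick_message(ids, rng_seed, prev_id)
}

#' Recognize a behavior the user often or always does
#'
#' Invoked when the day's goal was met; mirrors
#' [select_behavior_advice()] with eligibility at often/always (3-4).
#'
#' @inheritParams select_behavior_advice
#' @export
select_behavior_praise <- function(response, catalog = default_message_catalog(),
                                   rng_seed = 1, prev_id = NULL) {
  ids <- eligible_entries(response, catalog, "behavior_praise", function(s) s >= 3)
  if (length(ids) == 0) {
    fb <- catalog$id[catalog$kind == "behavior_praise" & catalog$fallback]
    if (length(fb) == 0) stop_input("catalog has no praise fallback entry")
    return(fb[1])
  }
  pick_message(ids, rng_seed, prev_id)
}

#' No-change tolerances for weekly trend messages
#'
#' Week-over-week mean changes smaller in magnitude than the tolerance
#' are reported as stable, avoiding jitter-driven messages.
#' @param steps,kcal,sbp_m,dbp_m,sbp_n,dbp_n,weight_kg,glucose_mgdl
#'   per-parameter tolerances in the parameter's own units.
#' @export
change_tolerances <- function(steps = 200, kcal = 10, sbp_m = 1, dbp_m = 1,
                              sbp_n = 1, dbp_n = 1, weight_kg = 0.2,
                              glucose_mgdl = 2) {
  c(
    steps = steps, kcal = kcal, sbp_m = sbp_m, dbp_m = dbp_m,
    sbp_n = sbp_n, dbp_n = dbp_n, weight_kg = weight_kg,
    glucose_mgdl = glucose_mgdl
  )
}

#' Compose the weekly feedback summary
#'
#' Reports the week's mean steps per day, the number of days the goal was
#' achieved, per-parameter means, and — when a previous week is available
#' — one trend message per parameter with data, chosen by the sign of the
#' week-over-week mean change with a no-change tolerance.
#'
#' @param this_week a [summarize_period()] row for the completed week.
#' @param prev_week the preceding week's summary, or `NULL` (first week
#'   of use: trend messages are omitted, means still reported).
#' @param goal_state the week's [goal_state()].
#' @param days_achieved days (0-7) on which the valid step count reached
#'   the goal.
#' @param catalog a [message_catalog()].
#' @param tolerance a [change_tolerances()] vector.
#' @return list with `mean_steps`, `days_achieved`, `goal`, `means`
#'   (named vector) and `change_messages` (named id vector).
#' @export
compose_weekly_feedback <- function(this_week, prev_week = NULL, goal_state,
                                    days_achieved, catalog = default_message_catalog(),
                                    tolerance = change_tolerances()) {
  if (days_achieved < 0 || days_achieved > 7) stop_input("days_achieved must be 0-7")
  mean_col <- function(summary, p) {
    col <- if (p %in% c("steps", "kcal")) paste0("mean_", p) else paste0("mean_", p)
    summary[[col]]
  }
  params <- names(change_tolerances())
  means <- vapply(params, function(p) {
    v <- mean_col(this_week, p)
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
  msgs <- character(0)
  if (!is.null(prev_week)) {
    for (p in params) {
      now <- mean_col(this_week, p)
      before <- mean_col(prev_week, p)
      if (is.null(now) || is.null(before) || is.na(now) || is.na(before)) next
      delta <- now - before
      dir <- if (abs(delta) < tolerance[[p]]) "stable" else if (delta > 0) "increased" else "decreased"
      id <- catalog$id[catalog$kind == "weekly_change" & catalog$parameter == p &
        catalog$direction == dir]
      if (length(id)) msgs[p] <- id[1]
    }
  }
  list(
    mean_steps = this_week$mean_steps,
    days_achieved = as.integer(days_achieved),
    goal = goal_state$goal,
    means = means,
    change_messages = msgs
  )
}
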