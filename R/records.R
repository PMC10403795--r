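#' Daily device records: constructors, I/O, cleaning and windowing
#'
#' A participant-day of device data is one row of a `daily_records` data
#' frame with columns `participant_id`, `date` (class `Date`), `steps`
#' (non-negative integer or `NA`), `worn` (logical or `NA`; self-reported
#' wear), `recording_failure` (logical; device/system failure not
#' attributable to the participant), morning and night systolic/diastolic
#' blood pressure `sbp_m`, `dbp_m`, `sbp_n`, `dbp_n` (mm Hg), `weight_kg`,
#' `glucose_mgdl` and `kcal_activity`.  Missing measurements are `NA`,
#' never zero.
#'
#' @name daily-records
NULL

RECORD_COLUMNS <- c(
  "participant_id", "date", "steps", "worn", "recording_failure",
  "sbp_m", "dbp_m", "sbp_n", "dbp_n", "weight_kg", "glucose_mgdl",
  "kcal_activity"
)

RECORD_NUMERIC <- setdiff(RECORD_COLUMNS, c("participant_id", "date", "worn", "recording_failure"))

#' Construct a validated daily-records table
#'
#' @param df data frame holding at least a `date` column; missing schema
#'   columns are added as all-`NA`.  Unknown columns are preserved.
#' @param participant_id default id used when `df` lacks the column.
#' @return a `daily_records` data frame sorted by participant and date.
#' @export
daily_records <- function(df, participant_id = "p1") {
  if (!is.data.frame(df)) stop_input("daily_records() expects a data frame")
  if (is.null(df$date)) stop_input("daily_records require a 'date' column")
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop_input("unparseable date in daily records")
  if (is.null(df$participant_id)) df$participant_id <- participant_id
  for (col in setdiff(RECORD_COLUMNS, names(df))) {
    df[[col]] <- if (col == "recording_failure") FALSE else NA
  }
  df$worn <- as.logical(df$worn)
  df$recording_failure <- isTRUE_vec(df$recording_failure)
  for (col in RECORD_NUMERIC) df[[col]] <- as.numeric(df[[col]])
  validate_daily_records(df)
  df <- df[order(df$participant_id, df$date), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("daily_records", "data.frame")
  df
}

isTRUE_vec <- function(x) {
  x <- as.logical(x)
  x[is.na(x)] <- FALSE
  x
}

validate_daily_records <- function(df) {
  if (any(df$steps < 0, na.rm = TRUE)) {
    stop_input("negative step counts are invalid")
  }
  dup <- duplicated(df[c("participant_id", "date")])
  if (any(dup)) {
    stop_input(
      "duplicate date(s) within a participant: %s",
      paste(format(df$date[dup]), collapse = ", ")
    )
  }
  for (col in c("sbp_m", "dbp_m", "sbp_n", "dbp_n")) {
    bad <- !is.na(df[[col]]) & (df[[col]] <= 0 | df[[col]] >= 400)
    if (any(bad)) {
      # stated policy: implausible BP is flagged, never auto-excluded
      warning(sprintf("%d implausible %s value(s) outside (0, 400) mm Hg", sum(bad), col),
        call. = FALSE
      )
    }
  }
  invisible(df)
}

#' Read daily device records from CSV
#'
#' One row per participant-day; empty cells become missing values.  Rows
#' with unparseable dates or numbers raise an error naming the line, and a
#' repeated date within one participant is a validation error.
#'
#' @param path CSV file with header columns as in [daily_records()].
#' @param format only `"csv"` is supported.
#' @return a `daily_records` data frame.
#' @export
load_daily_records <- function(path, format = c("csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("records file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (is.null(raw$date)) stop_input("records CSV lacks a 'date' column: %s", path)
  parsed <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(parsed)) {
    stop_input(
      "malformed date at line %s of %s",
      paste(which(is.na(parsed)) + 1L, collapse = ", "), path
    )
  }
  raw$date <- parsed
  for (col in intersect(RECORD_NUMERIC, names(raw))) {
    cell <- trimws(raw[[col]])
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & cell != "" & is.na(num))
    if (length(bad)) {
      stop_input("malformed value '%s' in column %s at line %d of %s",
        cell[bad[1]], col, bad[1] + 1L, path)
    }
    raw[[col]] <- num
  }
  for (col in intersect(c("worn", "recording_failure"), names(raw))) {
    cell <- tolower(trimws(raw[[col]]))
    val <- rep(NA, length(cell))
    val[cell %in% c("true", "t", "1", "yes")] <- TRUE
    val[cell %in% c("false", "f", "0", "no")] <- FALSE
    raw[[col]] <- val
  }
  daily_records(raw)
}

#' Write daily records to CSV using the documented schema
#' @param records a `daily_records` data frame.
#' @param path output file.
#' @export
write_daily_records <- function(records, path) {
  out <- as.data.frame(records)[RECORD_COLUMNS]
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Step-series cleaning rule
#'
#' Days are excluded from step analyses when the participant self-reported
#' not wearing the accelerometer or the daily count fell below
#' `min_valid_steps` (default 100; the exclusion is strictly-less-than, so
#' a 100-step day is retained).  A missing `worn` flag is treated as worn:
#' only affirmative self-reported non-wear excludes a day.
#'
#' @param min_valid_steps minimum retained daily step count.
#' @param require_worn drop days with `worn == FALSE`.
#' @export
cleaning_rule <- function(min_valid_steps = 100, require_worn = TRUE) {
  if (!is_scalar_number(min_valid_steps) || min_valid_steps <= 0) {
    stop_input("min_valid_steps must be a positive number")
  }
  structure(
    list(min_valid_steps = min_valid_steps, require_worn = isTRUE(require_worn)),
    class = "cleaning_rule"
  )
}

#' Clean a step series for analysis
#'
#' @param records a `daily_records` data frame.
#' @param rule a [cleaning_rule()].
#' @return the subset of `records` with steps present, not self-reported
#'   non-wear, and steps at or above the validity floor.  Idempotent.
#' @export
clean_step_series <- function(records, rule = cleaning_rule()) {
  stopifnot(inherits(rule, "cleaning_rule"))
  keep <- !is.na(records$steps) & records$steps >= rule$min_valid_steps
  if (rule$require_worn) keep <- keep & !(records$worn %in% FALSE)
  records[keep, , drop = FALSE]
}

#' Study-period windows
#'
#' Study day 1 is the first day of the 2-week baseline device period
#' (`P0b`, days 1-14).  A 5-day non-study interval follows, so
#' intervention day 1 is study day `15 + gap_days`.  Intervention week `w`
#' is the consecutive 7-day block starting there; the step-outcome windows
#' are `P1b` (intervention weeks 5-6) and `P2b` (weeks 23-24).
#'
#' @param label period name.
#' @param start_day,end_day inclusive study-day indices.
#' @export
study_period <- function(label, start_day, end_day) {
  if (!is_scalar_number(start_day) || !is_scalar_number(end_day) || start_day > end_day ||
    start_day < 1) {
    stop_input("invalid study period [%s, %s]", start_day, end_day)
  }
  structure(
    list(label = label, start_day = as.integer(start_day), end_day = as.integer(end_day)),
    class = "study_period"
  )
}

#' @rdname study_period
#' @param weeks_from,weeks_to inclusive intervention-week range.
#' @param gap_days non-study days between baseline and intervention.
#' @export
intervention_weeks <- function(weeks_from, weeks_to = weeks_from, gap_days = 5) {
  start <- 14 + gap_days + (weeks_from - 1) * 7 + 1
  end <- 14 + gap_days + weeks_to * 7
  study_period(sprintf("weeks %d-%d", weeks_from, weeks_to), start, end)
}

#' @rdname study_period
#' @export
standard_periods <- function(gap_days = 5) {
  list(
    P0b = study_period("P0b", 1, 14),
    P1b = intervention_weeks(5, 6, gap_days),
    P2b = intervention_weeks(23, 24, gap_days)
  )
}

#' Load named study periods from a YAML file
#'
#' The file maps period labels either to `[start_day, end_day]` pairs or
#' to `{weeks: [from, to]}` intervention-week ranges.
#' @param path YAML file.
#' @param gap_days non-study days between baseline and intervention.
#' @export
load_periods <- function(path, gap_days = 5) {
  spec <- yaml::read_yaml(path)
  lapply(stats::setNames(names(spec), names(spec)), function(lab) {
    entry <- spec[[lab]]
    if (is.list(entry) && !is.null(entry$weeks)) {
      p <- intervention_weeks(entry$weeks[[1]], entry$weeks[[length(entry$weeks)]], gap_days)
      p$label <- lab
      p
    } else {
      study_period(lab, entry[[1]], entry[[2]])
    }
  })
}

#' Restrict records to a study period
#'
#' @param records a `daily_records` data frame (one participant).
#' @param period a [study_period()].
#' @param start_date calendar date of study day 1; defaults to the
#'   earliest record date.
#' @export
window_period <- function(records, period, start_date = NULL) {
  stopifnot(inherits(period, "study_period"))
  if (nrow(records) == 0) return(records)
  if (is.null(start_date)) start_date <- min(records$date)
  day_index <- as.integer(records$date - as.Date(start_date)) + 1L
  records[day_index >= period$start_day & day_index <= period$end_day, , drop = FALSE]
}

#' Measurement adherence over a period
#'
#' Percentage of period days on which a parameter was measured and
#' recorded.  Days lost to recording failures, for which the participant
#' is not responsible, are removed from the denominator.
#'
#' @param records one participant's `daily_records`.
#' @param period a [study_period()].
#' @param parameter column to assess (e.g. `"steps"`, `"sbp_m"`, `"weight_kg"`).
#' @param start_date calendar date of study day 1.
#' @return percentage in `[0, 100]`.
#' @export
adherence_percentage <- function(records, period, parameter = "steps", start_date = NULL) {
  if (!parameter %in% RECORD_NUMERIC) stop_input("unknown parameter '%s'", parameter)
  if (is.null(start_date)) {
    if (nrow(records) == 0) stop_input("empty records and no start_date")
    start_date <- min(records$date)
  }
  win <- window_period(records, period, start_date)
  n_days <- period$end_day - period$start_day + 1L
  n_fail <- sum(win$recording_failure & is.na(win[[parameter]]))
  denom <- n_days - n_fail
  if (denom <= 0) stop_input("adherence undefined: all period days are recording failures")
  recorded <- sum(!is.na(win[[parameter]]))
  100 * recorded / denom
}

#' Is a data-entry reminder due?
#'
#' A reminder is sent when no accelerometer (step) data were recorded for
#' the 3 consecutive days ending yesterday.  With fewer than 3 days of
#' history no reminder is due.
#'
#' @param records one participant's `daily_records`.
#' @param today current calendar date.
#' @param run_days consecutive unrecorded days that trigger the reminder.
#' @export
reminder_due <- function(records, today, run_days = 3) {
  today <- as.Date(today)
  window <- today - seq_len(run_days)
  if (nrow(records) == 0) return(FALSE)
  if (min(records$date) > min(window)) return(FALSE) # not enough history
  recorded_dates <- records$date[!is.na(records$steps)]
  !any(window %in% recorded_dates)
}

#' Per-parameter period summary
#'
#' Arithmetic means over valid days only, with the number of contributing
#' days per parameter.  Steps and activity calories are first passed
#' through [clean_step_series()]; other parameters use all recorded days.
#' A parameter with no valid day yields `NA`, never zero.
#'
#' @param records one participant's `daily_records`.
#' @param period a [study_period()].
#' @param rule step [cleaning_rule()].
#' @param start_date calendar date of study day 1.
#' @return a one-row data frame with `mean_<param>` and `n_<param>` columns.
#' @export
summarize_period <- function(records, period, rule = cleaning_rule(), start_date = NULL) {
  if (is.null(start_date) && nrow(records) > 0) start_date <- min(records$date)
  win <- window_period(records, period, start_date)
  stepwise <- clean_step_series(win, rule)
  mean_or_na <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_
  out <- data.frame(
    period = period$label,
    mean_steps = mean_or_na(stepwise$steps),
    n_steps = sum(!is.na(stepwise$steps)),
    mean_kcal = mean_or_na(stepwise$kcal_activity),
    n_kcal = sum(!is.na(stepwise$kcal_activity)),
    stringsAsFactors = FALSE
  )
  for (col in c("sbp_m", "dbp_m", "sbp_n", "dbp_n", "weight_kg", "glucose_mgdl")) {
    out[[paste0("mean_", col)]] <- mean_or_na(win[[col]])
    out[[paste0("n_", col)]] <- sum(!is.na(win[[col]]))
  }
  out
}
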