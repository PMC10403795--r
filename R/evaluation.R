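#' Evaluation statistics for single-arm before-and-after step studies
#'
#' Paired changes are tested with the Wilcoxon signed rank test (exact
#' small-sample p-values, normal approximation with tie and continuity
#' corrections otherwise), summarized as the median change with a
#' distribution-free order-statistic confidence interval, and judged at a
#' Bonferroni-corrected per-test significance level (two tests per
#' outcome: short-term and long-term).
#'
#' @name evaluation
NULL

#' Evaluation configuration
#'
#' @param alpha_overall familywise two-sided significance level.
#' @param tests_per_outcome number of contrasts per outcome sharing the
#'   Bonferroni budget.
#' @param ci_level nominal confidence level of the median CI.
#' @param subgroup_threshold steps/day cut splitting the cohort into
#'   less-active and more-active subgroups.
#' @param mcid_steps minimal clinically important difference in
#'   steps/day; see [derive_mcid()].
#' @param assumed_sd assumed SD of the step change for sample-size
#'   planning.
#' @param stage_exclusion stage of change excluded from the main
#'   analysis population.
#' @param baseline_step_exclusion baseline mean above which participants
#'   are excluded (already at the maximum settable goal).
#' @export
eval_config <- function(alpha_overall = 0.05, tests_per_outcome = 2,
                        ci_level = 0.95, subgroup_threshold = 10000,
                        mcid_steps = derive_mcid(), assumed_sd = 1800,
                        stage_exclusion = "precontemplation",
                        baseline_step_exclusion = 15000) {
  structure(
    list(
      alpha_overall = alpha_overall,
      tests_per_outcome = tests_per_outcome,
      alpha_per_test = alpha_overall / tests_per_outcome,
      ci_level = ci_level,
      subgroup_threshold = subgroup_threshold,
      mcid_steps = mcid_steps,
      assumed_sd = assumed_sd,
      stage_exclusion = stage_exclusion,
      baseline_step_exclusion = baseline_step_exclusion
    ),
    class = "eval_config"
  )
}

#' Minimal clinically important difference in daily steps
#'
#' A 10-minute/day increase in moderate physical activity at a moderate
#' walking cadence of 100 steps/min corresponds to 1000 steps/day.
#'
#' @param minutes_per_day recommended daily activity increase (minutes).
#' @param cadence moderate-intensity walking cadence (steps/minute).
#' @export
derive_mcid <- function(minutes_per_day = 10, cadence = 100) {
  minutes_per_day * cadence
}

#' Main-population eligibility filter
#'
#' Retains participants outside the excluded stage of change (the engine
#' targets contemplation/preparation; precontemplation is excluded) whose
#' baseline mean does not exceed the maximum settable goal.
#'
#' @param participants data frame with `id` and `stage`.
#' @param baseline_means named numeric vector (names = participant ids).
#' @param config an [eval_config()].
#' @return the retained subset of `participants`.
#' @export
eligibility_filter <- function(participants, baseline_means, config = eval_config()) {
  if (anyNA(participants$stage)) stop_input("every participant needs a stage of change")
  if (!all(participants$stage %in% STAGES)) {
    stop_input("unknown stage(s): %s",
      paste(setdiff(unique(participants$stage), STAGES), collapse = ", "))
  }
  bm <- baseline_means[participants$id]
  keep <- participants$stage != config$stage_exclusion &
    !is.na(bm) & bm <= config$baseline_step_exclusion
  participants[keep, , drop = FALSE]
}

#' Wilcoxon signed rank test
#'
#' Zero differences are discarded; tied absolute differences receive
#' midranks.  For n at most `exact_max` the two-sided p-value is exact,
#' computed from the full sign-flip distribution of the positive-rank
#' sum (a convolution over doubled midranks, so ties are handled
#' exactly); otherwise the normal approximation with tie correction and
#' a continuity correction is used.
#'
#' @param before,after paired numeric vectors.
#' @param exact_max largest post-removal n for which the exact
#'   distribution is enumerated.
#' @return list with `statistic` (positive-rank sum W+), `n` (pairs after
#'   zero removal), `p_value`, `method` (`"exact"`, `"normal_approx"`, or
#'   `"degenerate"`), and `all_zero` flag.
#' @export
wilcoxon_signed_rank <- function(before, after, exact_max = 25) {
  if (length(before) != length(after)) stop_input("before/after must pair up")
  d <- as.numeric(after) - as.numeric(before)
  d <- d[!is.na(d)]
  if (length(d) == 0) stop_input("no complete pairs")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p-value is 1", call. = FALSE)
    return(list(statistic = 0, n = 0L, p_value = 1, method = "degenerate", all_zero = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, W)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- W - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2) # continuity correction toward the mean
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(statistic = W, n = as.integer(n), p_value = p, method = method, all_zero = FALSE)
}

# exact two-sided p for the positive-rank sum under random sign flips.
# Midranks are doubled to integers; the distribution of 2*W+ is built by
# dynamic programming (polynomial multiplication), equivalent to full
# enumeration of the 2^n sign assignments.
signed_rank_exact_p <- function(ranks, W) {
  s <- as.integer(round(2 * ranks))
  total <- sum(s)
  counts <- numeric(total + 1) # counts[k+1] = #assignments with 2*W+ = k
  counts[1] <- 1
  for (si in s) {
    shifted <- c(rep(0, si), counts[seq_len(total + 1 - si)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(s)
  w2 <- round(2 * W)
  p_le <- sum(probs[seq_len(w2 + 1)])
  p_ge <- sum(probs[(w2 + 1):(total + 1)])
  min(1, 2 * min(p_le, p_ge))
}

#' Distribution-free confidence interval for the median
#'
#' Returns the symmetric order-statistic interval `(x_(k), x_(n+1-k))`
#' with the largest `k` whose exact binomial(n, 1/2) coverage is at least
#' `level`.  When even the full range `(x_(1), x_(n))` falls short of the
#' nominal level (small n), that range is returned with
#' `below_nominal = TRUE` and the achieved coverage reported.
#'
#' @param values numeric vector (NAs dropped).
#' @param level nominal confidence level.
#' @return list with `lower`, `upper`, `k`, `coverage`, `below_nominal`.
#' @export
median_ci_distribution_free <- function(values, level = 0.95) {
  x <- sort(as.numeric(values[!is.na(values)]))
  n <- length(x)
  if (n == 0) stop_input("median CI requires at least one value")
  coverage_k <- function(k) 1 - 2 * stats::pbinom(k - 1, n, 0.5)
  ks <- seq_len(max(1, floor(n / 2)))
  cov <- vapply(ks, coverage_k, numeric(1))
  ok <- which(cov >= level)
  if (length(ok)) {
    k <- max(ok)
    list(
      lower = x[k], upper = x[n + 1 - k], k = k,
      coverage = cov[k], below_nominal = FALSE
    )
  } else {
    list(
      lower = x[1], upper = x[n], k = 1L,
      coverage = max(cov[1], 0), below_nominal = TRUE
    )
  }
}

#' Paired change summary for one outcome
#'
#' Median of (after - before) with its distribution-free CI, the Wilcoxon
#' signed rank p-value, and significance at the Bonferroni per-test
#' level.
#'
#' @param before,after paired outcome values; pairs with a missing side
#'   are dropped.
#' @param config an [eval_config()].
#' @return a `change_result` list: `n`, `median_change`, `ci_low`,
#'   `ci_high`, `coverage`, `below_nominal`, `p_value`, `significant`,
#'   `method`.
#' @export
paired_change_summary <- function(before, after, config = eval_config()) {
  if (length(before) != length(after)) stop_input("before/after must pair up")
  keep <- !is.na(before) & !is.na(after)
  before <- before[keep]
  after <- after[keep]
  if (length(before) == 0) stop_input("no complete pairs")
  d <- after - before
  test <- wilcoxon_signed_rank(before, after)
  ci <- median_ci_distribution_free(d, config$ci_level)
  structure(
    list(
      n = length(d),
      median_change = stats::median(d),
      ci_low = ci$lower, ci_high = ci$upper,
      coverage = ci$coverage, below_nominal = ci$below_nominal,
      p_value = test$p_value,
      significant = test$p_value < config$alpha_per_test,
      method = test$method
    ),
    class = "change_result"
  )
}

#' Split participants by baseline activity
#'
#' Less-active vs more-active subgroups around `subgroup_threshold`
#' steps/day; a baseline mean exactly at the threshold goes to the
#' less-active group (documented tie rule).
#'
#' @param baseline_means named numeric vector.
#' @param config an [eval_config()].
#' @return list with `low` and `high` id vectors.
#' @export
subgroup_split <- function(baseline_means, config = eval_config()) {
  ids <- names(baseline_means)
  if (is.null(ids)) ids <- as.character(seq_along(baseline_means))
  low <- baseline_means <= config$subgroup_threshold
  list(low = ids[low & !is.na(low)], high = ids[!low & !is.na(low)])
}

#' Outcome-specific medication exclusion
#'
#' Participants reporting the start of a new medication or a dose
#' increase for hypertension (or dyslipidemia) during follow-up are
#' excluded from home-BP (or lipid) analyses; dose decreases do not
#' exclude.
#'
#' @param participants cohort data frame with `med_bp_week`,
#'   `med_bp_type`, `med_lipid_week`, `med_lipid_type`.
#' @param outcome `"bp"` or `"lipids"`.
#' @return the retained subset.
#' @export
medication_exclusion <- function(participants, outcome = c("bp", "lipids")) {
  outcome <- match.arg(outcome)
  week_col <- if (outcome == "bp") "med_bp_week" else "med_lipid_week"
  type_col <- if (outcome == "bp") "med_bp_type" else "med_lipid_type"
  wk <- participants[[week_col]]
  ty <- participants[[type_col]]
  excl <- !is.na(wk) & ty %in% c("start", "increase")
  participants[!excl, , drop = FALSE]
}

#' Required sample size for a paired-difference t test
#'
#' Smallest n such that a two-sided one-sample (paired-difference) t test
#' of standardized effect size `dz` attains the target power, using the
#' noncentral t distribution with noncentrality `dz * sqrt(n)` and
#' `n - 1` degrees of freedom.
#'
#' @param effect_size_dz standardized paired effect size (mean change /
#'   SD of change).
#' @param power target power in (0, 1).
#' @param alpha two-sided significance level in (0, 1).
#' @param n_max search cap.
#' @return smallest integer n attaining the power.
#' @export
required_sample_size <- function(effect_size_dz, power = 0.80, alpha = 0.05,
                                 n_max = 1e6) {
  if (!is_scalar_number(effect_size_dz) || effect_size_dz <= 0) {
    stop_input("effect size dz must be positive")
  }
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1) {
    stop_input("power and alpha must lie strictly between 0 and 1")
  }
  power_at <- function(n) {
    tc <- stats::qt(1 - alpha / 2, n - 1)
    ncp <- effect_size_dz * sqrt(n)
    stats::pt(tc, n - 1, ncp, lower.tail = FALSE) + stats::pt(-tc, n - 1, ncp)
  }
  # exponential then binary search for the smallest attaining n
  lo <- 2
  if (power_at(lo) >= power) return(2L)
  hi <- 4
  while (power_at(hi) < power) {
    lo <- hi
    hi <- hi * 2
    if (hi > n_max) stop_input("required sample size exceeds %s", n_max)
  }
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (power_at(mid) >= power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

#' Per-participant baseline (P0b) step means
#'
#' @param records multi-participant `daily_records`.
#' @param rule a [cleaning_rule()].
#' @param start_date calendar date of study day 1.
#' @return named vector of cleaned P0b mean steps/day.
#' @export
baseline_step_means <- function(records, rule = cleaning_rule(), start_date = NULL) {
  period <- standard_periods()$P0b
  ids <- unique(records$participant_id)
  vapply(stats::setNames(ids, ids), function(pid) {
    rec <- records[records$participant_id == pid, , drop = FALSE]
    summarize_period(rec, period, rule, start_date = start_date)$mean_steps
  }, numeric(1))
}

outcome_column <- function(outcome) {
  switch(outcome,
    steps = "mean_steps", kcal = "mean_kcal",
    sbp_m = "mean_sbp_m", dbp_m = "mean_dbp_m",
    sbp_n = "mean_sbp_n", dbp_n = "mean_dbp_n",
    weight = "mean_weight_kg",
    stop_input("unknown outcome '%s'", outcome)
  )
}

#' Evaluate a trial dataset
#'
#' Applies the main-population eligibility filter, computes per-outcome
#' paired change summaries for the short-term (P0b to weeks 5-6) and
#' long-term (P0b to weeks 23-24) contrasts, applies the
#' medication-based analysis-set rule to BP outcomes, and returns one
#' row per outcome per contrast.
#'
#' @param trial a `trial_dataset` from [run_trial()] or assembled from
#'   files.
#' @param config an [eval_config()].
#' @param outcomes outcome names (see [outcome_column()] choices).
#' @param rule step [cleaning_rule()].
#' @return data frame with outcome, contrast, n, median change, CI
#'   bounds, achieved coverage, p-value and significance flag.
#' @export
evaluate_trial <- function(trial, config = eval_config(),
                           outcomes = c("steps", "kcal", "sbp_m", "dbp_m", "sbp_n", "dbp_n", "weight"),
                           rule = cleaning_rule()) {
  records <- trial$records
  start_date <- trial$start_date %||% min(records$date)
  periods <- standard_periods()
  bm <- baseline_step_means(records, rule, start_date)
  main <- eligibility_filter(trial$users, bm, config)

  summaries <- lapply(stats::setNames(names(periods), names(periods)), function(pl) {
    do.call(rbind, lapply(main$id, function(pid) {
      rec <- records[records$participant_id == pid, , drop = FALSE]
      s <- summarize_period(rec, periods[[pl]], rule, start_date = start_date)
      s$participant_id <- pid
      s
    }))
  })

  rows <- list()
  for (outcome in outcomes) {
    col <- outcome_column(outcome)
    pop <- if (outcome %in% c("sbp_m", "dbp_m", "sbp_n", "dbp_n")) {
      medication_exclusion(main, "bp")$id
    } else {
      main$id
    }
    for (contrast in c("P1b", "P2b")) {
      base <- summaries$P0b[[col]][match(pop, summaries$P0b$participant_id)]
      post <- summaries[[contrast]][[col]][match(pop, summaries[[contrast]]$participant_id)]
      ok <- !is.na(base) & !is.na(post)
      if (sum(ok) == 0) next
      cr <- paired_change_summary(base[ok], post[ok], config)
      rows[[length(rows) + 1]] <- data.frame(
        outcome = outcome,
        contrast = paste0("P0b_to_", contrast),
        n = cr$n, median_change = cr$median_change,
        ci_low = cr$ci_low, ci_high = cr$ci_high,
        coverage = cr$coverage, below_nominal = cr$below_nominal,
        p_value = cr$p_value, significant = cr$significant,
        method = cr$method,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Post hoc subgroup analysis of the step change
#'
#' Splits the main population at the baseline-activity threshold and
#' reports the paired step-change summary within each subgroup for both
#' contrasts.
#'
#' @inheritParams evaluate_trial
#' @export
evaluate_step_subgroups <- function(trial, config = eval_config(), rule = cleaning_rule()) {
  records <- trial$records
  start_date <- trial$start_date %||% min(records$date)
  periods <- standard_periods()
  bm <- baseline_step_means(records, rule, start_date)
  main <- eligibility_filter(trial$users, bm, config)
  groups <- subgroup_split(bm[main$id], config)
  rows <- list()
  for (grp in c("low", "high")) {
    ids <- groups[[grp]]
    if (length(ids) == 0) next
    for (contrast in c("P1b", "P2b")) {
      base <- vapply(ids, function(pid) {
        rec <- records[records$participant_id == pid, , drop = FALSE]
        summarize_period(rec, periods$P0b, rule, start_date)$mean_steps
      }, numeric(1))
      post <- vapply(ids, function(pid) {
        rec <- records[records$participant_id == pid, , drop = FALSE]
        summarize_period(rec, periods[[contrast]], rule, start_date)$mean_steps
      }, numeric(1))
      ok <- !is.na(base) & !is.na(post)
      if (sum(ok) == 0) next
      cr <- paired_change_summary(base[ok], post[ok], config)
      rows[[length(rows) + 1]] <- data.frame(
        subgroup = grp, contrast = paste0("P0b_to_", contrast),
        n = cr$n, median_change = cr$median_change,
        ci_low = cr$ci_low, ci_high = cr$ci_high,
        p_value = cr$p_value, significant = cr$significant,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Process evaluation: measurement adherence
#'
#' Per-participant step-measurement adherence during the baseline device
#' period and the whole intervention, with cohort medians.
#'
#' @inheritParams evaluate_trial
#' @param parameter records column whose adherence is assessed.
#' @export
process_evaluation <- function(trial, parameter = "steps") {
  records <- trial$records
  start_date <- trial$start_date %||% min(records$date)
  weeks <- trial$weeks %||% 24
  p0b <- standard_periods()$P0b
  interv <- intervention_weeks(1, weeks)
  ids <- unique(records$participant_id)
  per <- do.call(rbind, lapply(ids, function(pid) {
    rec <- records[records$participant_id == pid, , drop = FALSE]
    data.frame(
      participant_id = pid,
      adherence_P0b = adherence_percentage(rec, p0b, parameter, start_date),
      adherence_intervention = adherence_percentage(rec, interv, parameter, start_date),
      stringsAsFactors = FALSE
    )
  }))
  list(
    per_participant = per,
    median_P0b = stats::median(per$adherence_P0b),
    median_intervention = stats::median(per$adherence_intervention)
  )
}
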