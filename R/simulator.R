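#' Self-efficacy-mediated behavioral simulator
#'
#' Synthetic participants carry a latent log-normal baseline step
#' distribution and a self-efficacy state (0-100).  During the
#' intervention, an active goal adds `effort = responsiveness *
#' achievement_drive` steps to each day, where the drive is a logistic
#' function of the gap between self-efficacy and the goal's difficulty
#' (difficulty = goal excess over the baseline mean, in ladder
#' increments).  Weekly, the user reports a confidence that is a noisy
#' copy of self-efficacy discounted by difficulty, the goal engine runs
#' its suggest/assess/adjust session, and self-efficacy moves up by
#' `mastery_gain` after a goal-met week (mastery experience) or down by
#' `failure_loss` otherwise.  The full study timeline is a 2-week
#' baseline device period with the engine inactive, a 5-day non-study
#' interval, then 24 intervention weeks.
#'
#' @name simulator
NULL

#' Simulator configuration
#'
#' Defaults emulate the study population the engine targets: workers
#' whose baseline step counts are right-skewed with a median near 10,000
#' steps/day, high wear adherence, and a goal-related self-efficacy
#' around 70%.
#'
#' @param target_baseline_median cohort median of daily steps at
#'   baseline.
#' @param between_log_sd between-user SD of log baseline mean (0.22
#'   reproduces an interquartile spread of roughly 8500-11,600).
#' @param within_log_sd day-to-day SD of log steps within a user.
#' @param self_efficacy_mean,self_efficacy_sd initial latent
#'   self-efficacy (percent).
#' @param responsiveness ability ceiling: maximum extra steps/day an
#'   active goal can elicit.
#' @param effort_margin steps/day by which users aim past the goal gap
#'   (habitual overshoot that makes modest goals reliably achievable).
#' @param drive_slope slope of the logistic achievement drive.
#' @param efficacy_scale self-efficacy units per difficulty increment in
#'   the drive and confidence models.
#' @param conf_slope confidence discount (percent) per difficulty
#'   increment above 1.
#' @param conf_noise_sd SD of weekly confidence reporting noise.
#' @param mastery_gain,failure_loss self-efficacy change after goal-met /
#'   goal-missed weeks.
#' @param wear_prob daily probability of valid accelerometer wear.
#' @param recording_failure_prob daily probability of a device/system
#'   recording failure (not attributable to the user).
#' @param dropout_hazard per-week probability of dropping out.
#' @param bp_response mm Hg systolic decrease per 1000 sustained extra
#'   steps/day.
#' @param weight_response kg decrease per 1000 sustained extra steps/day
#'   over 24 weeks.
#' @param bp_record_prob daily probability a BP pair is recorded.
#' @param glucose_user_prob fraction of users asked to measure glucose.
#' @param seasonal_amplitude optional sinusoidal modulation of daily
#'   steps (fraction of baseline; default 0 = off).
#' @param gap_days non-study days between baseline and intervention.
#' @param stage_probs named probabilities for the five stages of change.
#' @export
sim_config <- function(target_baseline_median = 10000,
                       between_log_sd = 0.22,
                       within_log_sd = 0.25,
                       self_efficacy_mean = 72,
                       self_efficacy_sd = 10,
                       responsiveness = 2200,
                       effort_margin = 700,
                       drive_slope = 0.6,
                       efficacy_scale = 10,
                       conf_slope = 3,
                       conf_noise_sd = 4,
                       mastery_gain = 2,
                       failure_loss = 4,
                       wear_prob = 0.97,
                       recording_failure_prob = 0.01,
                       dropout_hazard = 0.0015,
                       bp_response = 2,
                       weight_response = 1,
                       bp_record_prob = 0.95,
                       glucose_user_prob = 0.3,
                       seasonal_amplitude = 0,
                       gap_days = 5,
                       stage_probs = c(
                         precontemplation = 0.10, contemplation = 0.15,
                         preparation = 0.50, action = 0.10, maintenance = 0.15
                       )) {
  cfg <- as.list(environment())
  probs <- cfg$stage_probs
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop_input("stage_probs must be non-negative and sum to 1")
  }
  for (p in c("wear_prob", "recording_failure_prob", "dropout_hazard",
              "bp_record_prob", "glucose_user_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop_input("%s must lie in [0, 1]", p)
  }
  if (cfg$target_baseline_median <= 0 || cfg$within_log_sd < 0 ||
      cfg$between_log_sd < 0 || cfg$responsiveness < 0) {
    stop_input("invalid simulator configuration")
  }
  structure(cfg, class = "sim_config")
}

#' Load a simulator configuration from YAML
#' @param path YAML file whose fields override [sim_config()] defaults.
#' @export
load_sim_config <- function(path) {
  spec <- yaml::read_yaml(path)
  if (!is.null(spec$stage_probs)) spec$stage_probs <- unlist(spec$stage_probs)
  do.call(sim_config, spec[intersect(names(spec), names(formals(sim_config)))])
}

STAGES <- c("precontemplation", "contemplation", "preparation", "action", "maintenance")

#' Generate a synthetic cohort
#'
#' Reproducible under `seed`; each user receives a latent baseline
#' distribution, an initial self-efficacy, demographic attributes, a
#' stage of change, and rare medication-change events used by the
#' evaluation module's analysis-set rules.
#'
#' @param n number of participants.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data frame of `sim_user` rows.
#' @export
generate_cohort <- function(n, config = sim_config(), seed = 1) {
  if (!is_scalar_number(n) || n < 1) stop_input("cohort size must be >= 1")
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(n)
  with_seed(seed, {
    id <- sprintf("p%03d", seq_len(n))
    stage <- sample(STAGES, n, replace = TRUE, prob = config$stage_probs)
    med_bp_week <- ifelse(stats::runif(n) < 0.05, sample(2:24, n, replace = TRUE), NA)
    med_bp_type <- ifelse(is.na(med_bp_week), NA,
      sample(c("start", "increase", "decrease"), n, replace = TRUE, prob = c(.5, .3, .2))
    )
    med_lipid_week <- ifelse(stats::runif(n) < 0.03, sample(2:24, n, replace = TRUE), NA)
    med_lipid_type <- ifelse(is.na(med_lipid_week), NA,
      sample(c("start", "increase"), n, replace = TRUE)
    )
    data.frame(
      id = id,
      sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.63, 0.37)),
      age = round(stats::rnorm(n, 52.9, 5.3), 1),
      stage = stage,
      # -within^2/2 so a median user's *mean* daily steps equals the target
      baseline_log_mean = stats::rnorm(
        n, log(config$target_baseline_median) - config$within_log_sd^2 / 2,
        config$between_log_sd
      ),
      baseline_log_sd = config$within_log_sd,
      self_efficacy = clamp(stats::rnorm(n, config$self_efficacy_mean, config$self_efficacy_sd), 0, 100),
      responsiveness = config$responsiveness,
      mastery_gain = config$mastery_gain,
      failure_loss = config$failure_loss,
      wear_prob = config$wear_prob,
      dropout_hazard = config$dropout_hazard,
      sbp0 = stats::rnorm(n, 133, 7),
      dbp0 = stats::rnorm(n, 89, 5),
      weight0 = round(stats::rnorm(n, 66, 10), 1),
      glucose_user = stats::runif(n) < config$glucose_user_prob,
      med_bp_week = med_bp_week,
      med_bp_type = med_bp_type,
      med_lipid_week = med_lipid_week,
      med_lipid_type = med_lipid_type,
      stringsAsFactors = FALSE
    )
  })
}

# logistic achievement drive in [0, 1]
achievement_drive <- function(self_efficacy, difficulty, config) {
  stats::plogis(config$drive_slope * (self_efficacy / config$efficacy_scale - difficulty))
}

# reported confidence: noisy copy of self-efficacy discounted by goal
# difficulty (percent)
report_confidence <- function(self_efficacy, difficulty, config) {
  clamp(
    self_efficacy - config$conf_slope * config$efficacy_scale / 10 *
      (difficulty - 1) + stats::rnorm(1, 0, config$conf_noise_sd),
    0, 100
  )
}

goal_difficulty <- function(goal, baseline_mean, increment) {
  (goal - baseline_mean) / increment
}

# one day-block of raw device measurements (vectorized over days)
simulate_days <- function(user, n_days, effort, day_offset, config) {
  steps_latent <- exp(stats::rnorm(n_days, user$baseline_log_mean, user$baseline_log_sd))
  if (config$seasonal_amplitude > 0) {
    phase <- 2 * pi * (day_offset + seq_len(n_days)) / 365
    steps_latent <- steps_latent * (1 + config$seasonal_amplitude * cos(phase))
  }
  steps <- round(pmax(steps_latent + effort, 0))
  worn <- stats::runif(n_days) < user$wear_prob
  failure <- stats::runif(n_days) < config$recording_failure_prob
  steps[!worn | failure] <- NA
  data.frame(
    steps = steps,
    worn = ifelse(failure, NA, worn),
    recording_failure = failure,
    kcal_activity = ifelse(is.na(steps), NA, round(steps * 0.03 + stats::rnorm(n_days, 0, 8)))
  )
}

add_physio <- function(days_df, user, extra_steps_per_day, week_frac, config) {
  n <- nrow(days_df)
  bp_drop <- config$bp_response * extra_steps_per_day / 1000
  rec <- stats::runif(n) < config$bp_record_prob
  sbp_m <- round(user$sbp0 - bp_drop + stats::rnorm(n, 0, 6), 1)
  dbp_m <- round(user$dbp0 - 0.6 * bp_drop + stats::rnorm(n, 0, 4), 1)
  days_df$sbp_m <- ifelse(rec, sbp_m, NA)
  days_df$dbp_m <- ifelse(rec, dbp_m, NA)
  rec_n <- stats::runif(n) < config$bp_record_prob
  days_df$sbp_n <- ifelse(rec_n, round(user$sbp0 - 6 - bp_drop + stats::rnorm(n, 0, 6), 1), NA)
  days_df$dbp_n <- ifelse(rec_n, round(user$dbp0 - 9 - 0.6 * bp_drop + stats::rnorm(n, 0, 4), 1), NA)
  wt <- user$weight0 - config$weight_response * extra_steps_per_day / 1000 * week_frac +
    stats::rnorm(n, 0, 0.3)
  days_df$weight_kg <- ifelse(stats::runif(n) < 0.95, round(wt, 1), NA)
  days_df$glucose_mgdl <- if (isTRUE(user$glucose_user)) {
    ifelse(stats::runif(n) < 0.9, round(stats::rnorm(n, 90, 6)), NA)
  } else {
    NA_real_
  }
  days_df
}

#' Simulate one user's full study trajectory
#'
#' @param user one row of [generate_cohort()] (data frame or list).
#' @param engine_config a [goal_config()].
#' @param weeks number of intervention weeks.
#' @param seed integer seed.
#' @param config a [sim_config()].
#' @param start_date calendar date of study day 1.
#' @return list with `records` (a `daily_records` data frame), `goals`
#'   (per-week trace: goal, source, confidence, verdicts, days achieved,
#'   self-efficacy), and `dropout_week` (`NA` if completed).
#' @export
simulate_user_weeks <- function(user, engine_config = goal_config(), weeks = 24,
                                seed = 1, config = sim_config(),
                                start_date = as.Date("2018-11-05")) {
  if (weeks < 1) stop_input("weeks must be >= 1")
  user <- as.list(user)
  with_seed(seed, {
    # 2-week baseline + non-study gap: engine inactive, no goal effort
    base_df <- simulate_days(user, 14, effort = 0, day_offset = 0, config = config)
    base_df <- add_physio(base_df, user, 0, 0, config)
    gap_df <- simulate_days(user, config$gap_days, 0, 14, config)
    gap_df <- add_physio(gap_df, user, 0, 0, config)

    baseline_clean <- base_df$steps[!is.na(base_df$steps) & base_df$steps >= 100 &
      !(base_df$worn %in% FALSE)]
    baseline_mean <- if (length(baseline_clean)) mean(baseline_clean) else exp(user$baseline_log_mean)

    se <- user$self_efficacy
    prev_state <- NULL
    prev_perf <- NULL
    week_rows <- list()
    day_blocks <- list(base_df, gap_df)
    dropout_week <- NA_integer_

    for (w in seq_len(weeks)) {
      if (stats::runif(1) < user$dropout_hazard) {
        dropout_week <- w
        break
      }
      suggestion <- if (w == 1) {
        suggest_week1_goal(baseline_mean, engine_config)
      } else {
        suggest_next_goal(prev_state, prev_perf, engine_config)
      }
      proposal <- suggestion
      adjusted <- FALSE
      conf <- NA_real_
      # at most 2 assess-adjust rounds, then the last answer stands
      for (round in 1:2) {
        diff_now <- goal_difficulty(proposal, baseline_mean, engine_config$increment)
        conf <- report_confidence(se, diff_now, config)
        verdict <- assess_confidence(conf, engine_config)
        if (verdict == "appropriate") break
        proposal <- adjust_goal(proposal, verdict, engine_config)
        adjusted <- TRUE
      }
      state <- finalize_goal(proposal, w,
        adjusted = adjusted, confidence = conf,
        config = engine_config
      )

      difficulty <- goal_difficulty(state$goal, baseline_mean, engine_config$increment)
      drive <- achievement_drive(se, difficulty, config)
      # striving is aimed at the goal gap (plus habitual overshoot) and
      # capped by ability; a null engine (responsiveness 0) elicits none
      aim <- clamp(state$goal - baseline_mean + config$effort_margin, 0, user$responsiveness)
      effort <- aim * drive
      wdf <- simulate_days(user, 7, effort, 14 + config$gap_days + (w - 1) * 7, config)
      wdf <- add_physio(wdf, user, effort, w / weeks, config)
      day_blocks[[length(day_blocks) + 1]] <- wdf

      valid <- !is.na(wdf$steps) & wdf$steps >= 100 & !(wdf$worn %in% FALSE)
      days_achieved <- sum(valid & wdf$steps >= state$goal)
      mean_steps <- if (any(valid)) mean(wdf$steps[valid]) else 0
      # mastery experience on goal-met weeks; failure experience only on
      # clearly failed weeks (middling weeks leave self-efficacy alone)
      se <- clamp(
        se + if (days_achieved >= engine_config$raise_threshold_days) {
          user$mastery_gain
        } else if (days_achieved <= 1) {
          -user$failure_loss
        } else {
          0
        },
        0, 100
      )

      week_rows[[w]] <- data.frame(
        week = w, suggested = suggestion, goal = state$goal, source = state$source,
        confidence = conf, days_achieved = days_achieved,
        mean_steps = mean_steps, self_efficacy = se,
        stringsAsFactors = FALSE
      )
      prev_state <- state
      prev_perf <- week_performance(mean_steps, days_achieved, state$goal)
    }

    all_days <- do.call(rbind, day_blocks)
    all_days$date <- start_date + seq_len(nrow(all_days)) - 1
    all_days$participant_id <- user$id %||% "sim"
    list(
      records = daily_records(all_days),
      goals = if (length(week_rows)) do.call(rbind, week_rows) else NULL,
      baseline_mean = baseline_mean,
      dropout_week = dropout_week,
      final_self_efficacy = se
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ordinal item generator: Binomial(levels-1, p) shifted to `min_level`
ordinal_items <- function(n_items, p, min_level = 0, levels = 5) {
  min_level + stats::rbinom(n_items, levels - 1, p)
}

# questionnaire battery for one user at one time point; `engagement`
# shifts behavior/self-regulation frequencies upward on the logit scale
simulate_questionnaire <- function(user, baseline_mean, engagement, config) {
  p_beh <- stats::plogis(stats::qlogis(0.3) + engagement +
    (user$self_efficacy - config$self_efficacy_mean) / 50)
  behavior <- behavior_response(stats::setNames(
    ordinal_items(32, p_beh),
    essmbpa_items()
  ))
  pasr <- ordinal_items(12, stats::plogis(stats::qlogis(0.35) + engagement), min_level = 1)
  confs <- vapply(goal_se_targets(), function(g) {
    report_confidence(
      user$self_efficacy,
      goal_difficulty(g, baseline_mean, 1000), config
    )
  }, numeric(1))
  list(
    behavior = behavior,
    pasr = pasr,
    goal_confidences = round(clamp(confs, 0, 100) / 5) * 5,
    walking_se = ordinal_items(4, stats::plogis(stats::qlogis(0.4) + engagement / 2), min_level = 1),
    pain = ordinal_items(4, 0.12, min_level = 1)
  )
}

#' Run a full virtual trial
#'
#' Simulates every cohort member through baseline plus `weeks`
#' intervention weeks and collects the artifacts the evaluation module
#' consumes: daily records, weekly goal traces, and questionnaire
#' batteries at P0a (before), P1a (after 6 weeks) and P2a (end).
#'
#' @param cohort a [generate_cohort()] data frame.
#' @param engine_config a [goal_config()].
#' @param seed integer seed; fans out to per-user child seeds.
#' @param weeks intervention weeks.
#' @param config a [sim_config()].
#' @param start_date calendar date of study day 1.
#' @return a `trial_dataset` list: `records`, `goals`, `questionnaires`,
#'   `users`, `weeks`, `start_date`.
#' @export
run_trial <- function(cohort, engine_config = goal_config(), seed = 1, weeks = 24,
                      config = sim_config(), start_date = as.Date("2018-11-05")) {
  if (nrow(cohort) == 0) stop_input("cohort is empty")
  recs <- list()
  goals <- list()
  quest <- list()
  for (i in seq_len(nrow(cohort))) {
    user <- cohort[i, ]
    res <- simulate_user_weeks(user, engine_config, weeks,
      seed = derive_seed(seed, i), config = config,
      start_date = start_date
    )
    recs[[i]] <- res$records
    if (!is.null(res$goals)) {
      g <- res$goals
      g$participant_id <- user$id
      goals[[i]] <- g
    }
    quest[[i]] <- with_seed(derive_seed(seed, 100000 + i), {
      engaged <- if (config$responsiveness > 0) 0.8 else 0
      lapply(
        stats::setNames(
          c(0, engaged, engaged * 0.9),
          c("P0a", "P1a", "P2a")
        ),
        function(e) simulate_questionnaire(as.list(user), res$baseline_mean, e, config)
      )
    })
  }
  all_records <- do.call(rbind, recs)
  class(all_records) <- c("daily_records", "data.frame")
  structure(
    list(
      records = all_records,
      goals = do.call(rbind, goals),
      questionnaires = stats::setNames(quest, cohort$id),
      users = cohort,
      weeks = weeks,
      start_date = start_date,
      engine_config = engine_config,
      sim_config = config
    ),
    class = "trial_dataset"
  )
}
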