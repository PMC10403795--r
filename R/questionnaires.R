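#' Questionnaire specifications and scoring
#'
#' Four instruments are scored:
#'
#' * **ES-SMBPA-2D** — 32 items in 9 factors rating the frequency of
#'   physical-activity self-management behaviors on a 5-level scale
#'   (never = 0 ... always = 4); factor scores are item sums with the
#'   ranges shown in [essmbpa_factors()].
#' * **PASR-12** — physical-activity self-regulation, 6 factors of 2
#'   items each on a 1-5 Likert scale; factor range 2-10, total 12-60.
#' * **Goal-related self-efficacy** — confidence (0-100%) of achieving
#'   each of 4 incremental step goals (6000, 8000, 10,000, 12,000
#'   steps/day); the score is the mean of the 4 confidences.
#' * **Walking self-efficacy** — confidence of walking in 4 difficult
#'   situations, 1-5 each, summed (range 4-20); and a 4-item body-pain
#'   cluster on the same scale.
#'
#' @name questionnaires
NULL

#' ES-SMBPA-2D factor structure
#'
#' @return data frame with `factor`, `n_items` and the item-sum `range`
#'   implied by 0-4 item scoring.
#' @export
essmbpa_factors <- function() {
  data.frame(
    factor = c(
      "shopping", "household", "exertion", "commuting",
      "suitable_place_time", "self_monitoring", "making_habit",
      "exercising_for_eating", "creating_situation"
    ),
    n_items = c(4L, 4L, 4L, 4L, 5L, 3L, 3L, 2L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Item ids of the 32 ES-SMBPA-2D items, in factor order
#' @export
essmbpa_items <- function() {
  spec <- essmbpa_factors()
  unlist(lapply(seq_len(nrow(spec)), function(i) {
    paste0(spec$factor[i], "_", seq_len(spec$n_items[i]))
  }), use.names = FALSE)
}

essmbpa_item_factor <- function() {
  spec <- essmbpa_factors()
  rep(spec$factor, spec$n_items)
}

#' 5-level frequency labels used for behavior items
#' @export
frequency_levels <- function() c("never", "rarely", "sometimes", "often", "always")

#' A validated ES-SMBPA-2D behavior response
#'
#' @param scores named numeric vector of the 32 item scores on the 0-4
#'   frequency scale (`NA` = explicitly missing), or a character vector of
#'   [frequency_levels()] labels.  Names must be [essmbpa_items()].
#' @return a `behavior_response` object (named numeric vector).
#' @export
behavior_response <- function(scores) {
  items <- essmbpa_items()
  if (is.character(scores)) {
    lv <- match(scores, frequency_levels()) - 1
    names(lv) <- names(scores)
    scores <- lv
  }
  if (is.null(names(scores)) && length(scores) == length(items)) names(scores) <- items
  if (!setequal(names(scores), items)) {
    stop_input("behavior response must cover exactly the 32 ES-SMBPA-2D items")
  }
  ordered <- as.numeric(scores[match(items, names(scores))])
  names(ordered) <- items
  if (any(ordered < 0 | ordered > 4, na.rm = TRUE)) {
    stop_input("item scores must lie on the 0-4 frequency scale")
  }
  structure(ordered, class = "behavior_response")
}

#' Impute missing behavior items from the factor mean
#'
#' Each missing item is replaced by the mean of the observed items in the
#' same factor at the same time point; fractional values are retained.
#' Observed items are never altered, so complete factors pass through
#' unchanged.  A factor with no observed item stays missing and raises a
#' warning (its factor score is then missing).
#'
#' @param response a [behavior_response()].
#' @return imputed `behavior_response`.
#' @export
impute_factor_items <- function(response) {
  stopifnot(inherits(response, "behavior_response"))
  fac <- essmbpa_item_factor()
  out <- unclass(response)
  for (f in unique(fac)) {
    idx <- which(fac == f)
    vals <- out[idx]
    if (all(is.na(vals))) {
      warning(sprintf("factor '%s' has no observed items; score left missing", f),
        call. = FALSE
      )
      next
    }
    out[idx][is.na(vals)] <- mean(vals, na.rm = TRUE)
  }
  structure(out, class = "behavior_response")
}

#' Score the study questionnaires
#'
#' @param behavior a [behavior_response()] (scored after
#'   [impute_factor_items()] if items are missing).
#' @param pasr named or unnamed numeric vector of the 12 PASR items
#'   (1-5), two per factor in the order self-monitoring, goal setting,
#'   eliciting social support, reinforcements, time management, relapse
#'   prevention; or `NULL`.
#' @param goal_confidences numeric vector of 4 confidences (0-100) for
#'   the 6000/8000/10,000/12,000 steps-per-day goals; or `NULL`.
#' @param walking_se numeric vector of 4 items (1-5); or `NULL`.
#' @param pain numeric vector of the 4 body-pain-cluster items (1-5); or
#'   `NULL`.
#' @return list of scores: `essmbpa` (named factor sums), `pasr_factors`,
#'   `pasr_total`, `goal_self_efficacy`, `walking_self_efficacy`,
#'   `pain_cluster`.
#' @export
score_questionnaires <- function(behavior = NULL, pasr = NULL,
                                 goal_confidences = NULL, walking_se = NULL,
                                 pain = NULL) {
  out <- list()
  if (!is.null(behavior)) {
    stopifnot(inherits(behavior, "behavior_response"))
    fac <- essmbpa_item_factor()
    sums <- c(tapply(unclass(behavior), fac, sum))
    out$essmbpa <- sums[essmbpa_factors()$factor]
  }
  if (!is.null(pasr)) {
    if (length(pasr) != 12) stop_input("PASR-12 requires 12 items")
    if (any(pasr < 1 | pasr > 5, na.rm = TRUE)) stop_input("PASR items must lie in 1-5")
    fac <- rep(c(
      "self_monitoring", "goal_setting", "eliciting_social_support",
      "reinforcements", "time_management", "relapse_prevention"
    ), each = 2)
    sums <- c(tapply(as.numeric(pasr), fac, sum))
    out$pasr_factors <- sums[unique(fac)]
    out$pasr_total <- sum(pasr)
  }
  if (!is.null(goal_confidences)) {
    if (length(goal_confidences) != 4) {
      stop_input("goal-related self-efficacy requires 4 confidence ratings")
    }
    if (any(goal_confidences < 0 | goal_confidences > 100, na.rm = TRUE)) {
      stop_input("confidences must lie in [0, 100]")
    }
    out$goal_self_efficacy <- mean(goal_confidences)
  }
  if (!is.null(walking_se)) {
    if (length(walking_se) != 4 || any(walking_se < 1 | walking_se > 5, na.rm = TRUE)) {
      stop_input("walking self-efficacy requires 4 items in 1-5")
    }
    out$walking_self_efficacy <- sum(walking_se)
  }
  if (!is.null(pain)) {
    if (length(pain) != 4 || any(pain < 1 | pain > 5, na.rm = TRUE)) {
      stop_input("pain cluster requires 4 items in 1-5")
    }
    out$pain_cluster <- sum(pain)
  }
  out
}

#' The 4 incremental step goals rated for goal-related self-efficacy
#' @export
goal_se_targets <- function() c(6000, 8000, 10000, 12000)
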