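test_that("eligibility keeps the engine's target population", {
  parts <- data.frame(
    id = c("a", "b", "c", "d"),
    stage = c("precontemplation", "preparation", "contemplation", "action"),
    stringsAsFactors = FALSE
  )
  bm <- c(a = 9000, b = 9500, c = 15200, d = 15000)
  kept <- eligibility_filter(parts, bm)
  expect_equal(kept$id, c("b", "d")) # precontemplation out; >15,000 out; =15,000 kept
  parts$stage[2] <- NA
  expect_error(eligibility_filter(parts, bm), "stage")
})

test_that("the signed rank test matches hand enumeration on the canonical example", {
  w <- wilcoxon_signed_rank(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$statistic, 6)
  expect_equal(w$p_value, 0.25)
  expect_equal(w$method, "exact")
  expect_warning(w0 <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(w0$p_value, 1)
  expect_true(w0$all_zero)
})

test_that("exact p-values agree with brute-force enumeration on random tied data", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(2:9, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3), n, replace = TRUE)
    got <- wilcoxon_signed_rank(rep(0, n), d)
    expect_equal(got$p_value, enumerate_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("untied exact p-values agree with the reference implementation", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    before <- rnorm(n)
    after <- before + rnorm(n)
    ours <- wilcoxon_signed_rank(before, after)
    ref <- stats::wilcox.test(after, before, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("the large-sample path matches the tie- and continuity-corrected normal approximation", {
  set.seed(4)
  for (i in 1:10) {
    n <- 30
    before <- round(rnorm(n, 100, 10))
    d <- round(rnorm(n, 1, 5)) # rounding creates ties in |d|
    d[d == 0] <- 1 # keep all 30 pairs on the large-sample path
    after <- before + d
    ours <- wilcoxon_signed_rank(before, after)
    expect_equal(ours$method, "normal_approx")
    ref <- suppressWarnings(
      stats::wilcox.test(after, before, paired = TRUE, exact = FALSE, correct = TRUE)
    )
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-6)
  }
})

test_that("median CIs take the widest order-statistic interval meeting the level", {
  ci <- median_ci_distribution_free(c(3, 1, 4, 1, 5, 9))
  expect_equal(ci$k, 1L)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 9)
  expect_equal(ci$coverage, 0.96875)
  expect_false(ci$below_nominal)
  ci5 <- median_ci_distribution_free(1:5)
  expect_true(ci5$below_nominal)
  expect_equal(ci5$coverage, 0.9375)
  expect_equal(median_ci_distribution_free(rep(2, 10))$lower, 2) # zero width
  expect_equal(median_ci_distribution_free(rep(2, 10))$upper, 2)
  # larger n permits k > 1; coverage still >= level
  ci30 <- median_ci_distribution_free(1:30)
  expect_gt(ci30$k, 1)
  expect_gte(ci30$coverage, 0.95)
  expect_error(median_ci_distribution_free(numeric(0)), "at least one")
})

test_that("paired change summaries combine median, CI and test correctly", {
  cr <- paired_change_summary(1:10, 1:10 + 1)
  expect_equal(cr$median_change, 1)
  expect_equal(cr$p_value, 2^-9)
  expect_true(cr$significant)
  cr0 <- suppressWarnings(paired_change_summary(1:8, 1:8))
  expect_equal(cr0$median_change, 0)
  expect_equal(cr0$p_value, 1)
  expect_false(cr0$significant)
  expect_true(cr0$ci_low <= cr0$median_change && cr0$median_change <= cr0$ci_high)
})

test_that("the median CI covers a pure location shift at roughly its achieved rate", {
  set.seed(19)
  hits <- 0
  reps <- 400
  for (i in 1:reps) {
    d <- rnorm(20, mean = 700, sd = 1800)
    ci <- median_ci_distribution_free(d)
    if (ci$lower <= 700 && 700 <= ci$upper) hits <- hits + 1
  }
  cov <- median_ci_distribution_free(rnorm(20))$coverage
  expect_gt(hits / reps, cov - 3 * sqrt(cov * (1 - cov) / reps) - 0.01)
})

test_that("subgroups split at 10,000 with the boundary going low", {
  g <- subgroup_split(c(a = 8000, b = 9000, c = 11000, d = 12000))
  expect_equal(g$low, c("a", "b"))
  expect_equal(g$high, c("c", "d"))
  expect_equal(subgroup_split(c(x = 10000))$low, "x")
  expect_length(subgroup_split(stats::setNames(numeric(0), character(0)))$low, 0)
})

test_that("medication changes exclude participants from the matching outcome only", {
  parts <- data.frame(
    id = c("a", "b", "c"),
    med_bp_week = c(10, NA, 12), med_bp_type = c("start", NA, "decrease"),
    med_lipid_week = c(NA, 8, NA), med_lipid_type = c(NA, "increase", NA),
    stringsAsFactors = FALSE
  )
  expect_equal(medication_exclusion(parts, "bp")$id, c("b", "c")) # decrease retained
  expect_equal(medication_exclusion(parts, "lipids")$id, c("a", "c"))
})

test_that("noncentral-t sample size reproduces the planning n and is monotone", {
  expect_equal(required_sample_size(0.55, 0.80, 0.05), 28L)
  expect_lt(required_sample_size(1.0, 0.80, 0.05), 28)
  expect_gt(required_sample_size(0.55, 0.90, 0.05), 28)
  expect_gt(required_sample_size(0.55, 0.80, 0.01), 28)
  # cross-check against the independent closed-form power routine
  for (dz in c(0.3, 0.55, 0.8)) {
    ref <- ceiling(stats::power.t.test(
      delta = dz, sd = 1, power = 0.8,
      type = "one.sample"
    )$n)
    expect_equal(required_sample_size(dz, 0.80, 0.05), ref)
  }
  expect_error(required_sample_size(-1), "positive")
})

test_that("location shifts are recovered by the paired summary", {
  set.seed(23)
  d0 <- rnorm(200, sd = 1800)
  cr <- paired_change_summary(d0, d0 + 1000 + rnorm(200, sd = 600))
  expect_lt(abs(cr$median_change - 1000) / 1000, 0.05)
  expect_true(cr$ci_low <= 1000 && 1000 <= cr$ci_high)
})
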