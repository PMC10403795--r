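---
title: "Adaptive step-goal coaching: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive step-goal coaching: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepcoach)
```

## The intervention model

stepcoach implements a fully automated weekly coaching loop for
increasing daily step count, grounded in Social Cognitive Theory (SCT).
Three SCT constructs shape the design. *Self-regulation* is supported by
self-monitoring (daily device records), self-set goals, and feedback.
*Self-efficacy* — the person's conviction that they can execute the
behavior — is targeted through graded goals that accumulate mastery
experiences and through positive feedback as verbal persuasion.
*Behavioral capability* is addressed by a 12-item action list and
barrier/solution catalogs. The engine's target population is people in
the contemplation and preparation stages of change; the evaluation
module's eligibility filter encodes exactly that.

### The goal ladder

Week 1 proposes `round_100(baseline mean) + 500` steps/day, where the
baseline mean is taken over the cleaned 2-week baseline device period.
From week 2 the previous week's achievement count steers the ladder:
raise one increment on ≥ 4 achieved days, hold on 2–3, lower on ≤ 1.
All goals are clamped to `[2000, 15000]`; 15,000 steps/day is both the
suggestion cap and the user-input cap. The underlying deployment did
not publish its suggestion arithmetic (it was tuned by simulation on
unpublished data), so the increment (500 steps), rounding unit (100),
floor (2,000) and the 4 / 2–3 / ≤ 1 day thresholds are package design
choices, held in `goal_config()` where every one of them can be
overridden. The raise threshold of 4 days deliberately matches the
framing of the confidence question (achieving the goal on more than
half the week's days), keeping the two halves of the engine consistent.

### The confidence band

Reported confidence of 70–90% marks a goal as appropriate; the band is
inclusive at both ends, and every confidence in [0, 100] maps to
exactly one verdict. Below-band confidence lowers the proposal one
increment. For above-band confidence the goal is *raised*: in
goal-setting terms, over-90% confidence means the goal is too easy to
be challenging. The direction for the over-confident case is a design
choice (the deployed system's behavior is not printed) and is the one
consistent with the band's "challenging yet attainable" semantics. A
weekly session runs at most two assess–adjust rounds, after which the
last answer stands; this guarantees termination and bounds oscillation.

### Feedback selection

Message catalogs carry identified entries: daily achieved/missed
variants, one advice and one praise entry per ES-SMBPA-2D behavior
item, generic fallbacks, and per-parameter weekly trend messages.
Advice is eligible only for items the user scores *never/rarely* (0–1
on the 0–4 frequency scale), praise only for *often/always* (3–4).
Selection is uniform over eligible entries under a caller-supplied
seed and avoids repeating the immediately preceding message when at
least two entries are eligible — the simplest policy that is fully
deterministic under a fixed seed, which in turn makes whole feedback
transcripts byte-reproducible. Weekly trend messages compare adjacent
weekly means with no-change tolerances (200 steps, 1 mm Hg, 0.2 kg,
10 kcal, 2 mg/dL) so measurement jitter does not produce
"increased/decreased" messages; the tolerances are configurable and
the defaults are chosen at roughly the day-to-day noise floor of each
measurement.

## Data cleaning and windows

A step day is valid when steps are recorded, the participant did not
self-report non-wear, and the count is ≥ 100 (strictly-below-100 days
are treated as non-wear artifacts). A missing wear flag counts as worn:
only affirmative self-reported non-wear excludes, which is the
conservative reading of the cleaning rule. Study day 1 is the first day
of the baseline device period (P0b, days 1–14); a 5-day non-study
interval follows, and intervention week *w* occupies the consecutive
7-day block from day `20 + 7(w−1)`. The step-outcome windows are
intervention weeks 5–6 and 23–24. Adherence is the percentage of
period days with a recording, after removing recording-failure days —
failures of the device or system, not the participant — from the
denominator.

## The behavioral simulator

The simulator exists to close the loop for end-to-end testing and
virtual trials; it deliberately does not attempt to reproduce any real
cohort's statistics.

Daily steps are log-normal (right-skewed, positive):
`steps = exp(N(μ_i, σ_w)) + effort`, with user-level `μ_i` drawn so the
cohort median of baseline means sits at the 10,000 steps/day scale of
the target population (between-user log-SD 0.22 gives a realistic
interquartile spread of roughly 8,500–11,600), and within-user
day-to-day log-SD 0.25. The `−σ_w²/2` correction makes the configured
target the median of *user means* rather than of latent medians.

Effort — the extra steps an active goal elicits — is
`drive · min(goal − baseline + margin, ability)`, where
`drive = plogis(0.6 (S/10 − difficulty))`, `S` is latent self-efficacy
(0–100), and difficulty is the goal's excess over the user's baseline
mean in ladder increments. Striving is thus *aimed at the goal* (one
does not walk 2,000 extra steps to satisfy a 500-step goal), overshoots
it by a habitual margin (700 steps/day by default), and is capped by an
ability ceiling (2,200 steps/day). The multiplicative drive carries the
SCT mechanism: low self-efficacy or an out-of-reach goal suppresses
striving. Setting `responsiveness = 0` (the ability ceiling) yields an
exact null engine, which the type-I-control tests exploit.

Weekly, reported confidence is a noisy copy of self-efficacy discounted
by difficulty (`S − 3(difficulty − 1) + N(0, 4)`, clamped). After each
week, mastery experience adds `mastery_gain` (default 2) to `S` on
goal-met weeks (≥ 4 achieved days); a *clearly failed* week (≤ 1
achieved days) subtracts `failure_loss` (default 4); middling weeks
leave `S` unchanged. Tying the failure update to clear failure rather
than to every non-met week mirrors the routing rule's notion of a
failed week and prevents ordinary week-to-week variability from
draining self-efficacy — with a symmetric update, average users drift
into chronic under-confidence and the engine spends the study lowering
goals, which is neither the intended mechanism nor realistic for a
population that volunteered to walk more.

Wear is Bernoulli per day (default 0.97, matching the high adherence
of worker cohorts with loaner devices); rare recording failures
(default 0.01/day) and a small weekly dropout hazard (0.0015) complete
the missingness model. Blood pressure and weight co-simulate as mild
linear responses to sustained extra steps with noise; they are
observational outputs, not calibrated targets. An optional seasonal
sinusoid on daily steps (default off) can emulate winter attenuation;
it is off by default so that core tests are not confounded.

What the simulator does *not* emulate: serial correlation in daily
steps, weekday/weekend structure, measurement error of the
accelerometer, floor/ceiling artifacts in questionnaires, or any
participant's real covariance between behavior and physiology. Passing
tests therefore demonstrate the engine's logic and the statistics'
calibration under a plausible generative model — not efficacy on real
data.

## Evaluation statistics

**Wilcoxon signed rank.** Zero differences are discarded (the classical
convention; a Pratt-style variant was considered and rejected to keep
the exact distribution simple and oracle-testable). Tied absolute
differences receive midranks. For n ≤ 25 the two-sided p-value is
exact: the distribution of the positive-rank sum over all 2ⁿ sign
assignments is built by convolution over doubled midranks, so tied data
also get exact p-values rather than falling back to the approximation.
Above that, the normal approximation with tie correction and a
continuity correction is used; the suite cross-checks both paths
against `stats::wilcox.test` and an independent brute-force
enumeration oracle.

**Median CI.** The distribution-free interval takes symmetric order
statistics `(x_(k), x_(n+1−k))` with the largest k whose exact
binomial(n, ½) coverage is ≥ the nominal level — the widest-k (hence
shortest) interval still meeting the level. No interpolation is used:
the method class is order statistics with exact coverage, and the
achieved coverage is always reported. For n ≤ 5 even the full range
cannot reach 95% (n = 5 achieves 0.9375); the interval is then the
range with `below_nominal = TRUE`, making the small-sample limitation
explicit rather than silent.

**Multiplicity.** Two contrasts per outcome (short-term and long-term)
share a 0.05 familywise budget, giving the .025 per-test level.

**Sample size.** The required n for a two-sided paired-difference
t test is the smallest n whose noncentral-t power (noncentrality
`dz·√n`, df `n−1`) reaches the target; at dz = 0.55 (the 1,000-step
minimal clinically important difference over an assumed 1,800-step SD),
80% power, and α = .05 this gives n = 28. The noncentral-t formulation
matches standard power software; the suite cross-checks it against
`stats::power.t.test`.

**Analysis sets.** The main population excludes the precontemplation
stage and baseline means above 15,000 steps/day (already at the input
cap). Participants starting or increasing an antihypertensive
(lipid-lowering) medication during follow-up are excluded from BP
(lipid) analyses only; dose decreases do not exclude. The post hoc
subgroup split at 10,000 steps/day assigns an exact-10,000 baseline to
the less-active group — the boundary is undefined in a strict
`<`/`>` split, and a fixed documented rule beats an ambiguous one.

**Imputation.** A missing behavior item takes the mean of the observed
items in its factor at the same time point, keeping fractional values;
observed items are never altered, and a fully missing factor stays
missing with a warning.

## Numerical and interface choices

* Rounding of goal proposals is half-away-from-zero on the configured
  unit, avoiding `round()`'s round-to-even surprises at midpoints.
* Seeded message selection restores the caller's RNG state, so feedback
  draws never perturb an enclosing simulation stream; one user-facing
  seed fans out to per-user/per-module child seeds through a fixed
  integer derivation, keeping every component independently
  reproducible and the simulate → coach → evaluate pipeline
  byte-identical under a fixed seed.
* Degenerate inputs are explicit: all-zero differences give p = 1 with
  a warning; an all-missing parameter yields a missing summary field,
  never zero; an empty eligible message set falls back to a generic
  entry; a records file ending mid-week skips the partial week with a
  warning.
* Implausible blood-pressure values (outside (0, 400) mm Hg) raise
  warnings but are never auto-excluded, since no BP cleaning rule is
  part of the contract; only presence/absence matters downstream.

## Problem sizes used in the shipped checks

The suite runs virtual trials at n = 30 users for calibration checks
(200 replicates of 6-week trials for type-I control), n = 60–100 users
for distributional and attenuation properties, 10⁴ Monte-Carlo draws
for CI coverage, and exhaustive enumeration up to n = 10 for the exact
test. These sizes are chosen to make Monte-Carlo error small relative
to the tested margins while keeping the default test run comfortably
interactive.

## Known limitations

The goal-suggestion arithmetic, routing thresholds, and feedback
"conditional equations" of the deployed system this package models are
not public; the package's versions are principled reconstructions with
every threshold exposed in configuration objects. The simulator's
self-efficacy dynamics are a minimal SCT-consistent coupling, not a
fitted behavioral model; its variance components are stated defaults,
not estimates. Questionnaire co-simulation produces valid, scoreable
responses with plausible improvement patterns but no factor structure
beyond independence. None of the statistical machinery addresses
seasonality, mixed models, or multiple imputation — deliberate
non-goals for a paired nonparametric evaluation.
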