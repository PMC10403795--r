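# stepcoach

An R implementation of a fully automated, Social-Cognitive-Theory-based
step-goal coaching engine for adults with high blood pressure, together
with a behavioral user simulator and the evaluation statistics used in
single-arm before-and-after step studies. It is aimed at digital-health
researchers who want to prototype, stress-test, and power adaptive
step-goal interventions at the desk, without device integrations or
participant data.

## What it does

**Coaching engine.** Each intervention week the engine proposes a daily
step goal: week 1 starts from the cleaned baseline mean, rounded to the
nearest 100 steps plus one 500-step increment; later weeks move the goal
one increment up when the previous goal was achieved on ≥ 4 days, hold
it on 2–3 achieved days, and lower it otherwise, always clamped to
[2,000, 15,000] steps/day. The user reports their confidence *c* ∈
[0, 100] of achieving the goal on more than half the week's days; the
goal is judged appropriate iff 70 ≤ *c* ≤ 90 (challenging yet
attainable), and otherwise adjusted one increment before it is
finalized (the user may always self-set a goal up to the 15,000 input
cap). Daily feedback praises achievement; missed days trigger advice
drawn from the behaviors the user *never/rarely* performs on a 32-item
physical-activity self-management questionnaire (ES-SMBPA-2D), achieved
days trigger recognition of a behavior the user performs
*often/always*. Weekly sessions route between action-plan review,
current-barrier problem-solving (clearly failed week) and
future-barrier anticipation (clearly successful week).

**Simulator.** Synthetic users carry a log-normal baseline step
distribution and a latent self-efficacy *S* ∈ [0, 100]. An active goal
elicits extra daily steps `effort = drive · min(goal − baseline +
margin, ability)` with `drive = logistic(0.6 · (S/10 − difficulty))`,
where difficulty is the goal's excess over baseline in ladder
increments; mastery experiences raise *S*, clear failures lower it.
This closes the loop engine → behavior → achievement → self-efficacy →
behavior, and reproduces the qualitative signature of such trials:
early step gains with high wear adherence, and attenuation when the
goal ladder overshoots ability.

**Evaluation statistics.** Wear-based step cleaning (self-reported
non-wear and days < 100 steps excluded), study windows (2-week baseline
P0b, intervention weeks 5–6 and 23–24), Wilcoxon signed rank tests with
exact small-sample p-values (full sign-flip distribution, midranks for
ties), distribution-free median confidence intervals from symmetric
order statistics with exact binomial(n, ½) coverage, Bonferroni .025
per-test significance, questionnaire factor scoring with within-factor
mean imputation, baseline-activity subgroup splits, and noncentral-t
sample-size calculation.

## Worked example

```r
library(stepcoach)

suggest_week1_goal(10020)          # week-1 goal from a 10,020-step baseline
#> [1] 10500

cmd_power()                        # planning: MCID 1000 steps / SD 1800
#> $effect_size_dz 0.556  $power 0.8  $alpha 0.05  $n_required 28

cohort <- generate_cohort(30, sim_config(), seed = 42)
trial  <- run_trial(cohort, goal_config(), seed = 42, weeks = 24)
evaluate_trial(trial, outcomes = c("steps", "sbp_m"))
#>  outcome   contrast  n median_change   ci_low  ci_high   p_value significant
#>    steps P0b_to_P1b 20       672.772 -228.786 1933.934 3.623e-02       FALSE
#>    steps P0b_to_P2b 20      1789.786  913.330 2439.324 2.098e-04        TRUE
#>    sbp_m P0b_to_P1b 17        -4.506   -5.583   -1.129 1.526e-04        TRUE
#>    sbp_m P0b_to_P2b 17        -4.529   -6.137   -1.301 4.578e-05        TRUE

process_evaluation(trial)$median_intervention
#> [1] 97.02381
```

`n = 20` reflects the main-population filter (precontemplation stage
and baseline means above the 15,000-step input cap are excluded);
`n = 17` additionally removes users with a new or increased
antihypertensive during follow-up. Each row is the median within-person
change from the baseline device period to the stated intervention
window, with its distribution-free 95% CI and the Wilcoxon signed rank
p-value judged at the Bonferroni-corrected .025 level. The adherence
figure is the cohort median percentage of intervention days with a step
recording (recording-failure days excluded from the denominator).

A shell entry point wraps the same functions:

```sh
scripts/stepcoach simulate --out trial_dir --n 30 --weeks 24 --seed 1
scripts/stepcoach coach    --data trial_dir --seed 1
scripts/stepcoach evaluate --data trial_dir
scripts/stepcoach power
```

## Package layout

* `R/records.R` — daily record I/O, cleaning, windows, adherence, reminders
* `R/goal_engine.R` — weekly goal ladder, confidence band, finalization
* `R/feedback.R`, `R/planning.R` — message catalogs, advice/praise selection, action plans, barriers
* `R/questionnaires.R` — instrument scoring and imputation
* `R/simulator.R` — cohorts, trajectories, virtual trials
* `R/evaluation.R` — tests, CIs, eligibility, subgroups, power
* `R/coach.R`, `R/cli.R` — replay engine and file-oriented entry points
* `vignettes/stepcoach-methods.Rmd` — the model, its assumptions, and design choices
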