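Package: stepcoach
Title: Adaptive Step-Goal Coaching, Behavioral Simulation, and Paired
    Nonparametric Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fully automated weekly step-goal coaching engine for
    physical-activity interventions in adults with high blood pressure,
    grounded in Social Cognitive Theory.  Suggests gradually incremented
    daily step goals from baseline accelerometer data, assesses the
    user's confidence against a 70-90 percent appropriateness band,
    selects positive-feedback and individualized-advice messages from
    behavior-frequency questionnaire responses, and routes weekly
    sessions between action planning and barrier problem-solving.  Ships
    a self-efficacy-mediated behavioral simulator that generates
    goal-responsive synthetic cohorts, plus the evaluation statistics
    used in single-arm before-and-after step studies: wear-based step
    cleaning, Wilcoxon signed rank tests with exact small-sample
    p-values, distribution-free order-statistic confidence intervals for
    the median, questionnaire factor scoring with within-factor mean
    imputation, and noncentral-t sample-size calculation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
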