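Package: adaptscreen
Title: Adaptive Mental-Health Screening with Recurrent Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for adaptive administration of the GAD-7, PHQ-9 and PSS-10
    screening instruments. Severity scores on a 0-100 scale (from a pluggable
    text scorer or a synthetic respondent model) are accumulated against
    ROC-derived per-question thresholds inside a partially observable decision
    process that asks one question at a time, commits disorder predictions at
    final cutoffs and stops as early as the rules permit. Includes a synthetic
    cohort generator, a recurrent actor-critic policy trained with a clipped
    surrogate policy-gradient objective, scripted baselines, and an evaluation
    suite (episode reward summaries, Tukey boxplot statistics, confusion-matrix
    agreement against the full static questionnaires).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
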