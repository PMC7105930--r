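Package: pollendiary
Title: Adherence and Pollen-Period Analysis for Allergy E-Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing daily electronic symptom diaries kept by
    patients with seasonal allergic rhinoconjunctivitis during the pollen
    season. Computes daily symptom and medication scores (Rhinoconjunctivitis
    Total Symptom Score, combined symptom and medication score, visual analog
    scale), decomposes each patient's prescription window into delayed start,
    reporting period, missing days and advanced end, and derives the three
    standard adherence ratios. Detects pollen periods (whole season, peak
    season, high days) from daily pollen-count series under EAACI and locally
    adapted criteria, stratifies adherence by pollen period, and runs the
    cohort-level analyses: adherence trajectories by reporting day with phase
    summaries, early-window prediction of total adherence (Spearman),
    postponed-reporting correlation, and Friedman tests with Bonferroni
    correction across period definitions. Includes a synthetic cohort
    generator with three-phase reporting behaviour, patient-level persistence,
    postponed entries, and pollen-driven symptom severities, so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
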