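---
title: "Methods: e-diary adherence metrics, pollen periods, and the cohort simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: e-diary adherence metrics, pollen periods, and the cohort simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollendiary)
```

## The monitoring model

A patient is prescribed a monitoring interval (the *prescription period*,
both ends inclusive) during which they are asked to fill in a daily
questionnaire: six symptom severities on a 4-grade scale (0 none, 1 mild,
2 moderate, 3 severe) for sneezing, rhinorrhea, nasal pruritus, nasal
congestion, itchy eyes and watery eyes; three medication intake indicators
(antihistamine, local corticosteroid, systemic corticosteroid); and a 0–10
visual analog scale. An entry may refer to the same day or to the previous
one (*postponed reporting*); anything later is invalid and
`validate_records()` rejects it. Duplicate entries for a day are resolved in
favour of the earliest entry day, which deterministically prefers
non-postponed data.

From the cleaned records, `summarize_reporting()` decomposes each
prescription period: the *reporting period* spans the first to the last
reported day; the gap before it is the *delayed reporting start*, the gap
after it the *advanced reporting end*; unreported days inside the reporting
period are *missing*. The three ratios are adherence (reporting days /
reporting period), adherence to prescription (reporting days / prescription
period) and postponed reporting (postponed / reporting days), each × 100.
Because the reporting period is a subset of the prescription span (once the
start/end gaps are floored at zero), adherence to prescription can never
exceed adherence. Patients occasionally report outside their prescribed
window; such records still anchor the reporting period — behaviour is what it
is — while the start/end gaps floor at zero, and the validation report flags
them.

Two consecutive unreported days trigger an automatic alert and four trigger a
phone call (`alert_days()` emits the dates; the package computes, never
sends). Percentages are carried at full precision; rounding to one decimal is
a rendering decision.

## Scores

RTSS is the plain sum of the six severities (0–18). The CSMS standard
publishes the 0–6 range without an explicit formula for the medication
component, so the package adopts the conventional decomposition
`dCSMS = dSS + dMS`: dSS is the mean of the six severities (0–3) and dMS is a
stepwise score where the highest medication class taken that day counts —
0 none, 1 antihistamine, 2 local corticosteroid, 3 systemic corticosteroid.
This reproduces the published range exactly and is monotone in both symptom
burden and treatment escalation. VAS is stored as reported.

## Pollen periods

All five built-in criteria (`builtin_criteria()`) are lower-bound threshold
rules on a gap-free daily grains/m³ series:

| name | rule |
|---|---|
| `eaaci_whole` | 5 of 7 consecutive days each ≥ 3 grains/m³, sum ≥ 30 |
| `local_whole` | 5 of 7 consecutive days each ≥ 10 grains/m³, sum ≥ 100 |
| `eaaci_peak` | 3 consecutive days each ≥ 50 grains/m³ |
| `local_peak` | 3 of 5 consecutive days each ≥ 50 grains/m³ |
| `eaaci_high_days` | single days ≥ 50 grains/m³ |

Two genuinely open design choices are exposed as flags rather than hidden:

* **Day-marking convention.** Published season tables report *multiple*
  intervals per definition, which implies day-level marking followed by run
  merging rather than a single start/end pair. The default (`"coverage"`)
  marks every day covered by at least one qualifying window as in-season;
  the alternative (`"qualifying_days"`) marks only the threshold-passing days
  inside qualifying windows. The conventions coincide for single-day criteria
  and differ in cumulative duration otherwise, so every report records which
  one produced it. Without the original count data neither convention can be
  singled out; both are first-class and tested against a brute-force
  classifier.
* **Window sum scope.** "5 days … each with ≥ 3 … and with a sum of ≥ 30" is
  read as a property of those qualifying days (default); summing over the
  whole window is available via `sum_scope = "window"`.

Intervals are maximal runs of in-season days: two reported intervals are
always separated by at least one out-of-season day, and fragmented seasons
stay fragmented (no gap-merging). Missing days in a pollen series are never
imputed silently; `read_pollen()` rejects gapped series and offers
`zero_fill = TRUE` with a warning.

`period_adherence()` restricts adherence to days lying in both the patient's
reporting period and the period's intervals. Whether the denominator should
intersect the reporting or the prescription period is not fixed by the
published definitions; the reporting period is the default (it matches
"considering the total reporting period") and `scope = "prescription"` is the
alternative. Patients with an empty intersection are flagged undefined and
excluded from cohort means and from the repeated-measures comparison (dropped
patients are counted).

## Trajectories, phases, and the early-window predictor

`adherence_by_reporting_day()` aligns patients on their first reported day
and computes, at each reporting-day index *t*, the percentage reporting among
patients whose reporting period still covers *t* — denominators shrink as
periods end. Phase boundaries default to A = indices 1–6, B = 7–46, C = 47+
(a first week of near-complete reporting, a ~40-day plateau, then slow
decline) and are parameters, not constants.

Two structural facts about this estimator matter for interpretation. The
index-1 value is 100% by construction (the first reported day defines the
alignment), and each patient's final index is likewise always reported. The
interior indices carry the behavioural signal; the parameter-recovery tests
therefore compare phase means computed on interior flags (dropping index 1
and each patient's last reported index), which are exactly Bernoulli under
the simulator.

The early-window predictor (`window_adherence()`,
`early_window_correlation()`) is per-patient adherence over reporting-day
indices 7–21 — the second and third recording week, interpreted on the same
index scale as the trajectory — rank-correlated (Spearman, midranks) with
total adherence. Patients whose reporting period ends before index 21 are
excluded by default; `incomplete = "prorate"` computes over the indices they
have. Note that total adherence *contains* the predictor window: even with no
between-patient heterogeneity the overlap alone induces a positive
correlation (≈ 0.5 for a 15-of-60-day window). A pure test of *predictive*
signal should therefore correlate the early window with adherence after
index 21, which is what the test suite does for the null case.

`compare_period_adherence()` runs the Friedman repeated-measures test across
period definitions and all pairwise Wilcoxon signed-rank tests with
Bonferroni multiplication capped at 1. When no patient shows any
within-patient variation the statistic is 0 and p = 1 by convention (the
chi-square ratio is otherwise 0/0). P-values below 0.001 render as "<.001";
machine-precision values are kept in all machine-readable output.

## The cohort simulator

The simulator exists so that every pipeline stage has a ground truth. Its
defaults are the study conditions the package is designed around, chosen once:

* **Season** (`season_params()`): a Gaussian main peak of 199 grains/m³ in
  late May (SD 14 days) plus a smaller June peak (90 grains/m³, SD 10 days)
  over March–September, with multiplicative lognormal noise of unit mean and
  CV 0.5 — a realistic Mediterranean grass season magnitude with a bimodal,
  fragmented peak structure.
* **Prescriptions** (`prescription_policy()`): 50–90 day windows (uniform),
  centred on the season peak with ±14 days of jitter.
* **Behaviour** (`behavior_params()`): a three-phase step function for the
  daily reporting probability with phase means 0.931 / 0.8365 / 0.7855 and
  phase lengths 6 / 40 days — a step function rather than a smooth decline,
  which keeps recovery tests sharp. The patient-level random effect
  ("persistence", default SD 1.5 on the logit scale) is *mean-preserving*:
  the phase location is solved numerically so the cohort-mean probability
  equals the configured phase value at any heterogeneity. Postponement
  (baseline 0.15) is coupled to the same random effect (coupling 1), so
  lapse-prone patients postpone more — the mechanism behind the negative
  postponed-vs-total correlation. Delayed starts and intended early stops are
  geometric (means 2 and 3 days).
* **Symptoms**: an ordinal-logit dose-response with linear predictor
  `log(1 + concentration)` plus a patient sensitivity intercept (SD 0.5);
  cut-points (2.2, 3.3, 5.2) place the modal severity at "moderate" around
  50 grains/m³. Medication is drawn conditional on the daily symptom score
  (logistic for antihistamine; corticosteroids only when dSS ≥ 2), and VAS is
  a noisy monotone rescaling of RTSS clipped to [0, 10].

The first active day is reported by construction — it realises the drawn
delayed start and defines the reporting period — while the last reported day
is stochastic (trailing unreported days are absorbed into the realised
advanced end). A consequence worth knowing: adherence as defined is slightly
above the daily reporting probability even for a homogeneous cohort, because
both endpoints of the reporting period are reported days. For a 60-day window
at probability 0.5 the expectation is ≈ 51%, not 50%. This is a property of
the metric, not an artefact of the generator, and it is why recovery tests
use interior flags.

What the simulator does *not* emulate: center effects, weekday/weekend entry
patterns, within-patient autocorrelation of lapses beyond the constant random
effect, medication feedback on next-day symptoms, or real pollen count
irregularities (calms, rain washout). Passing tests demonstrate that the
pipeline measures what the generator encodes, not that any particular cohort
behaves this way.

## Numerical and testing choices

Interval detection is vectorised (window matrix plus difference-array
coverage counting) and verified, under both conventions and both sum scopes,
against an independent loop-and-`rle` brute-force classifier on a thousand
random series of length ≤ 60 whose values straddle all three thresholds.
Statistical routines are delegated to base R (`cor.test`, `friedman.test`,
`wilcox.test`, with Bonferroni multiplication applied explicitly); the
Spearman route is cross-checked in the tests against a manual
midrank-and-Pearson computation on small tied datasets. Friedman calibration
is checked by simulation (K = 5 definitions, 50 patients, 1000 null
replicates; rejection rate required to sit in [0.03, 0.07] at α = 0.05).
Cohort-scale simulations in the tests use 40–200 patients — large enough for
the binomial and rank-correlation bounds asserted, small enough to keep the
suite fast. Zero-variance correlation inputs are flagged degenerate rather
than propagated as errors; zero reported days yield zero counts with a
`no_reports` flag rather than division by zero.

## Limitations

Published cohort-scale magnitudes (per-center mean adherence, season-table
interval counts, center contrasts between pollen periods) depend on the
original diary and 2016 pollen-count data, which are not redistributable;
this package reproduces the *methods* and verifies them on synthetic ground
truth instead. The CSMS medication ladder is the conventional reading of the
standard, not a published formula. The period-detection conventions are
explicit flags precisely because the published interval counts cannot
arbitrate between them.
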