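# pollendiary

Adherence and pollen-period analysis for allergy e-diaries.

Patients with seasonal allergic rhinoconjunctivitis are increasingly asked by
their allergist to keep a daily electronic diary of symptoms and medication
intake during the pollen season ("blended care"). Whether such monitoring
works depends on *adherence*: do patients actually fill in the diary, for how
long, and does their early behaviour predict how they will do overall?
`pollendiary` implements the full analysis pipeline for this question, for
biostatisticians and allergy researchers working with daily diary data:

* **Daily scores.** Rhinoconjunctivitis Total Symptom Score
  (RTSS = Σ of six 0–3 severities, range 0–18), combined symptom and
  medication score (CSMS = dSS + dMS, where dSS is the mean of the six
  severities and dMS ∈ {0,1,2,3} is the highest medication class taken that
  day; range 0–6), and the patient's 0–10 visual analog scale (VAS).
* **Adherence decomposition.** For each patient the prescription period
  splits into delayed reporting start, the reporting period (first to last
  reported day), and advanced reporting end; within the reporting period,
  days are reported or missing, and reported days entered the next day are
  postponed. The three ratios are
  *adherence* = reporting days / reporting period × 100,
  *adherence to prescription* = reporting days / prescription period × 100,
  *postponed reporting* = postponed days / reporting days × 100.
* **Pollen periods.** Sliding-window detection of the whole season, peak
  season and high pollen days from daily grains/m³ counts under EAACI and
  locally adapted criteria (e.g. EAACI whole season: 5 of 7 consecutive days
  each ≥ 3 grains/m³ with a sum ≥ 30), with interval counts and cumulative
  durations, and adherence stratified by period.
* **Cohort statistics.** Adherence trajectories by reporting day with the
  three engagement phases (A: initial, B: plateau, C: decline), Spearman
  correlation of day 7–21 adherence with total adherence, postponed-reporting
  correlation, and Friedman repeated-measures tests with Bonferroni-adjusted
  Wilcoxon post hocs across period definitions.
* **A synthetic cohort generator** with three-phase reporting behaviour,
  patient-level persistence, postponed entries, prescription windows of
  50–90 days, and pollen-driven ordinal symptom severities — so the entire
  pipeline is testable without patient data.

## Worked example

A patient is prescribed 54 days of monitoring, starts reporting 6 days late,
stops 5 days early, and misses 7 days in between:

```r
library(pollendiary)

w     <- prescription_window("P001", "2016-04-01", "2016-05-24")   # 54 days
days  <- seq(as.Date("2016-04-07"), as.Date("2016-05-19"), by = "day")
skip  <- days[c(5, 9, 14, 20, 21, 30, 38)]
diary <- diary_record("P001", days[!days %in% skip])

summarize_reporting(diary, w)
#>  prescription_days delayed_start_days advanced_end_days reporting_period_days
#>                 54                  6                 5                    43
#>  missing_days reporting_days adherence_pct adherence_to_prescription_pct
#>             7             36      83.72093                      66.66667
```

The reporting period lasts 43 days with 36 reporting days, so adherence is
36/43 × 100 ≈ 83.7% while adherence to prescription is 36/54 × 100 ≈ 66.7%.

At cohort scale, using the simulator (100 patients, default behaviour):

```r
sim  <- simulate_cohort(100, seed = 1)
summ <- summarize_reporting(sim$diary, sim$prescriptions)
mean(summ$adherence_pct)                          # 84.1
early_window_correlation(sim$diary, sim$prescriptions)
#>     rho  p_value     n n_excluded degenerate
#>   0.914 3.33e-40   100          0 FALSE
postponed_correlation(summ)
#>     rho  p_value ...
#>  -0.912 8.95e-40
```

Adherence in the second and third recording week strongly predicts total
adherence, and postponed reporting is inversely related to it — the behaviour
the simulator's persistence model is built to produce.

Pollen periods and the period-stratified comparison:

```r
detect_all_periods(sim$pollen)[, 1:3]
#>   criteria        n_intervals cumulative_days
#> 1 eaaci_whole               1              94
#> 2 local_whole               1              82
#> 3 eaaci_peak                2              57
#> 4 local_peak                1              65
#> 5 eaaci_high_days           5              61

bundle <- run_pipeline(pipeline_config(sim$diary, sim$prescriptions, sim$pollen))
bundle$comparison
#> Friedman repeated-measures comparison of adherence across 5 period definitions
#>   n = 100 patients (0 dropped with undefined cells)
#>   chi-squared = 100.064, df = 4, p = <.001
#>   post hoc: Wilcoxon signed-rank, Bonferroni-adjusted
#>     ...
```

`run_pipeline()` also writes per-patient summaries, the season table,
trajectory and score-trajectory CSVs, an analysis JSON, and (optionally)
figures, all stamped with the convention flags and seed that produced them.

## Documentation

The methods vignette (`vignettes/adherence-methods.Rmd`) describes the model
assumptions, the period-detection conventions and their consequences, the
simulator design, and known limitations.
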