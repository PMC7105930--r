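test_that("the worked 54-day example decomposes exactly", {
  fx <- fig1_cohort()
  s <- summarize_reporting(fx$records, fx$window)
  expect_equal(s$prescription_days, 54L)
  expect_equal(s$delayed_start_days, 6L)
  expect_equal(s$advanced_end_days, 5L)
  expect_equal(s$reporting_period_days, 43L)
  expect_equal(s$missing_days, 7L)
  expect_equal(s$reporting_days, 36L)
  expect_equal(s$adherence_pct, 36 / 43 * 100)
  expect_equal(s$adherence_to_prescription_pct, 36 / 54 * 100)
  expect_equal(s$postponed_pct, 0)
  # sum identity when all reports fall inside the window
  expect_equal(
    s$reporting_days + s$missing_days + s$delayed_start_days + s$advanced_end_days,
    s$prescription_days
  )
})

test_that("full reporting gives 100/100/0 and zero reporting gives flagged zeros", {
  w <- prescription_window("P1", "2016-05-01", "2016-05-30")
  full <- reports_on("P1", seq(w$start, w$end, by = "day"))
  s <- summarize_reporting(full, w)
  expect_equal(s$adherence_pct, 100)
  expect_equal(s$adherence_to_prescription_pct, 100)
  expect_equal(s$postponed_pct, 0)

  none <- summarize_reporting(full[0, ], w)
  expect_true(none$no_reports)
  expect_equal(none$reporting_days, 0L)
  expect_equal(none$adherence_pct, 0)
})

test_that("postponed entries count as reporting days but are tracked", {
  w <- prescription_window("P1", "2016-05-01", "2016-05-10")
  days <- seq(w$start, w$end, by = "day")
  recs <- diary_record("P1", days, entry_day = days + rep(c(0, 1), 5))
  s <- summarize_reporting(recs, w)
  expect_equal(s$reporting_days, 10L)
  expect_equal(s$postponed_days, 5L)
  expect_equal(s$postponed_pct, 50)
})

test_that("adherence-to-prescription never exceeds adherence on random cohorts", {
  set.seed(21)
  for (rep in 1:10) {
    sim <- simulate_cohort(8, seed = 300 + rep)
    s <- summarize_reporting(sim$diary, sim$prescriptions)
    expect_true(all(s$adherence_to_prescription_pct <= s$adherence_pct + 1e-9))
    inside <- s$reporting_days + s$missing_days + s$delayed_start_days +
      s$advanced_end_days
    expect_true(all(inside == s$prescription_days))
  }
})

test_that("period-restricted adherence matches direct counting", {
  w <- prescription_window("P1", "2016-06-01", "2016-06-30")
  d0 <- as.Date("2016-06-01")
  # patient reports 8 of the 10 days 2016-06-05..14, everything else too
  all_days <- seq(w$start, w$end, by = "day")
  missing <- as.Date(c("2016-06-07", "2016-06-12"))
  recs <- reports_on("P1", setdiff(all_days, missing))
  ten <- detect_periods(
    pollen_series(d0 + 0:29, c(rep(0, 4), rep(60, 10), rep(0, 16))),
    "eaaci_high_days"
  )
  pa <- period_adherence(recs, w, ten)
  expect_equal(pa$days_in_period, 10L)
  expect_equal(pa$reported_in_period, 8L)
  expect_equal(pa$adherence_pct, 80)

  # a period covering the whole reporting span reproduces overall adherence
  whole <- detect_periods(pollen_series(d0 + 0:29, rep(60, 30)), "eaaci_high_days")
  s <- summarize_reporting(recs, w)
  expect_equal(period_adherence(recs, w, whole)$adherence_pct, s$adherence_pct)

  # a disjoint period is undefined and flagged
  far <- detect_periods(
    pollen_series(as.Date("2016-08-01") + 0:9, rep(60, 10)), "eaaci_high_days"
  )
  pf <- period_adherence(recs, w, far)
  expect_false(pf$defined)
  expect_true(is.na(pf$adherence_pct))
})

test_that("alert and phone-call days follow the 2-day/4-day rules", {
  w <- prescription_window("P1", "2016-05-01", "2016-05-14")
  days <- seq(w$start, w$end, by = "day")

  expect_equal(nrow(alert_days(reports_on("P1", days), w)), 0)

  two_gap <- reports_on("P1", setdiff(days, days[5:6]))
  a2 <- alert_days(two_gap, w)
  expect_equal(a2$event, "alert")
  expect_equal(a2$date, days[6]) # second unreported day

  five_gap <- reports_on("P1", setdiff(days, days[5:9]))
  a5 <- alert_days(five_gap, w)
  expect_equal(a5$event, c("alert", "phone_call"))
  expect_equal(a5$date, c(days[6], days[8])) # gap days 2 and 4

  # two separate gaps each trigger their own alert; runs reset on reports
  split_gaps <- reports_on("P1", setdiff(days, days[c(3, 4, 8, 9)]))
  expect_equal(sum(alert_days(split_gaps, w)$event == "alert"), 2)
})

test_that("alerts are consistent with the missing-day count", {
  set.seed(22)
  sim <- simulate_cohort(10, seed = 77)
  s <- summarize_reporting(sim$diary, sim$prescriptions)
  al <- alert_days(sim$diary, sim$prescriptions)
  n_alerts <- sum(al$event == "alert")
  unreported <- sum(s$prescription_days) - sum(s$reporting_days)
  expect_true(unreported >= 2 * n_alerts)
})

test_that("the adherence trajectory counts reporters among patients still in period", {
  w <- prescription_window(c("A", "B"), rep("2016-05-01", 2),
                           c("2016-05-10", "2016-05-05"))
  dA <- seq(as.Date("2016-05-01"), as.Date("2016-05-10"), by = "day")
  dB <- seq(as.Date("2016-05-01"), as.Date("2016-05-05"), by = "day")
  recs <- dplyr::bind_rows(
    reports_on("A", dA),                 # full 10 days
    reports_on("B", dB[-3])             # misses index 3, period 5 days
  )
  tr <- adherence_by_reporting_day(recs, w)
  expect_equal(tr$pct[tr$index == 1], 100)
  expect_equal(tr$pct[tr$index == 3], 50)
  expect_equal(tr$n_at_risk[tr$index == 6], 1) # B's period has ended
  expect_equal(max(tr$index), 10)
  expect_equal(tr$phase[tr$index <= 6], rep("A", 6))
  expect_equal(tr$phase[tr$index > 6], rep("B", 4))
})

test_that("window adherence excludes or pro-rates short reporting periods", {
  w <- prescription_window(c("A", "B"), rep("2016-05-01", 2),
                           c("2016-06-30", "2016-05-15"))
  dA <- seq(as.Date("2016-05-01"), as.Date("2016-05-31"), by = "day")
  recs <- dplyr::bind_rows(
    reports_on("A", dA[-c(10, 11, 12)]),       # 12/15 in indices 7..21
    reports_on("B", seq(as.Date("2016-05-01"), as.Date("2016-05-15"), by = "day"))
  )
  ex <- window_adherence(recs, w, 7, 21)
  expect_equal(ex$patient_id, "A")
  expect_equal(ex$window_adherence_pct, 12 / 15 * 100)
  pr <- window_adherence(recs, w, 7, 21, incomplete = "prorate")
  expect_setequal(pr$patient_id, c("A", "B"))
  expect_equal(pr$window_adherence_pct[pr$patient_id == "B"], 100)
  expect_false(pr$complete[pr$patient_id == "B"])
})
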