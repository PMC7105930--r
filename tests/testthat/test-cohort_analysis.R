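test_that("Spearman route matches a manual midrank-and-Pearson computation", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    x <- sample(0:5, n, replace = TRUE) * 10 # ties on purpose
    y <- sample(0:5, n, replace = TRUE) * 10
    if (sd(x) == 0 || sd(y) == 0) next
    summ <- tibble::tibble(
      patient_id = paste0("P", seq_len(n)),
      postponed_pct = x, adherence_pct = y, no_reports = FALSE
    )
    got <- postponed_correlation(summ)
    expect_equal(got$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("early-window correlation is 1 under perfect rank agreement", {
  w <- prescription_window(c("A", "B", "C"), rep("2016-05-01", 3),
                           rep("2016-06-09", 3)) # 40 days
  days <- seq(as.Date("2016-05-01"), as.Date("2016-06-09"), by = "day")
  recs <- dplyr::bind_rows(
    reports_on("A", days),                 # early 15/15, total 40/40
    reports_on("B", setdiff(days, days[8:12])),   # early 10/15, total 35/40
    reports_on("C", setdiff(days, days[8:17]))    # early 5/15,  total 30/40
  )
  out <- early_window_correlation(recs, w)
  expect_equal(out$rho, 1)
  expect_equal(out$n, 3)
})

test_that("postponed correlation handles perfect inversion and degeneracy", {
  mk <- function(post, adh) tibble::tibble(
    patient_id = paste0("P", seq_along(post)),
    postponed_pct = post, adherence_pct = adh, no_reports = FALSE
  )
  inv <- postponed_correlation(mk(100 - c(70, 80, 90, 95), c(70, 80, 90, 95)))
  expect_equal(inv$rho, -1)
  deg <- postponed_correlation(mk(rep(10, 5), c(70, 80, 90, 95, 99)))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$rho))
  expect_error(postponed_correlation(mk(1, 2)), "insufficient")
})

test_that("identical adherence across definitions yields a null Friedman result", {
  dat <- tidyr::expand_grid(
    patient_id = paste0("P", 1:8),
    period = c("w", "x", "y")
  )
  dat$adherence_pct <- rep(c(70, 75, 80, 85, 90, 95, 60, 65), each = 3)
  cmp <- compare_period_adherence(dat)
  expect_equal(glance(cmp)$statistic, 0)
  expect_equal(glance(cmp)$p_value, 1)
  expect_true(all(tidy(cmp)$p_adjusted == 1))
})

test_that("a uniform +10 point shift in one definition is detected (n=20, K=2)", {
  base <- 60 + (1:20) * 1.5
  dat <- dplyr::bind_rows(
    tibble::tibble(patient_id = paste0("P", 1:20), period = "a", adherence_pct = base),
    tibble::tibble(patient_id = paste0("P", 1:20), period = "b", adherence_pct = base + 10)
  )
  cmp <- compare_period_adherence(dat)
  expect_lt(glance(cmp)$p_value, 0.05)
  expect_lt(tidy(cmp)$p_adjusted, 0.05)
})

test_that("Bonferroni adjustment multiplies and caps, never below raw", {
  set.seed(32)
  dat <- tidyr::expand_grid(patient_id = paste0("P", 1:15),
                            period = c("a", "b", "c", "d"))
  dat$adherence_pct <- runif(nrow(dat), 60, 100)
  cmp <- compare_period_adherence(dat)
  pw <- tidy(cmp)
  expect_equal(nrow(pw), choose(4, 2))
  expect_true(all(pw$p_adjusted >= pw$p_value))
  expect_equal(pw$p_adjusted, pmin(1, pw$p_value * choose(4, 2)))
})

test_that("patients with undefined cells are dropped and counted", {
  dat <- tidyr::expand_grid(patient_id = paste0("P", 1:6), period = c("a", "b"))
  dat$adherence_pct <- runif(nrow(dat), 50, 100)
  dat$adherence_pct[dat$patient_id == "P3" & dat$period == "b"] <- NA
  cmp <- compare_period_adherence(dat)
  expect_equal(cmp$n, 5)
  expect_equal(cmp$n_dropped, 1)
  expect_error(
    compare_period_adherence(dat[dat$period == "a", ]),
    "insufficient"
  )
})

test_that("score trajectories average reporters per date and leave gaps", {
  d0 <- as.Date("2016-06-01")
  recs <- dplyr::bind_rows(
    diary_record("A", d0, sneezing = 3, rhinorrhea = 3, vas = 4),      # RTSS 6
    diary_record("B", d0, sneezing = 3, rhinorrhea = 3, nasal_pruritus = 3,
                 nasal_congestion = 3, vas = 6),                       # RTSS 12
    diary_record("A", d0 + 2, sneezing = 1, vas = 1)                   # gap at d0+1
  )
  st <- score_trajectories(recs)
  expect_equal(st$rtss[st$day == d0], 9)
  expect_equal(st$n[st$day == d0], 2)
  expect_false((d0 + 1) %in% st$day)
  expect_equal(st$vas[st$day == d0], 5)

  # restriction to a period drops out-of-period dates
  p <- detect_periods(pollen_series(d0 + 0:1, c(60, 60)), "eaaci_high_days")
  st2 <- score_trajectories(recs, p)
  expect_equal(st2$day, d0)

  # single patient, constant scores -> flat trajectory
  flat <- diary_record("A", d0 + 0:4, sneezing = 2, vas = 3)
  stf <- score_trajectories(flat)
  expect_equal(unique(stf$rtss), 2)
  expect_equal(unique(stf$vas), 3)
  expect_equal(unique(stf$csms), 2 / 6)
})

test_that("trajectory phase means recover simulated three-phase probabilities", {
  # interior reporting flags (dropping each patient's definitional first and
  # last reported index) are exactly Bernoulli(p_phase)
  b <- behavior_params(persistence = 0, p_postpone = 0)
  sim <- simulate_cohort(40, behavior = b, seed = 501)
  flags <- reporting_flags(sim$diary, sim$prescriptions)
  interior <- flags |>
    dplyr::group_by(patient_id) |>
    dplyr::filter(index > 1, index < max(index[reported])) |>
    dplyr::ungroup()
  interior$phase <- cut(interior$index, c(0, 6, 46, Inf), labels = c("A", "B", "C"))
  truth <- c(A = b$p_phase_a, B = b$p_phase_b, C = b$p_phase_c)
  ph <- interior |>
    dplyr::group_by(phase) |>
    dplyr::summarise(p_hat = mean(reported), n = dplyr::n())
  for (i in seq_len(nrow(ph))) {
    p <- truth[[as.character(ph$phase[i])]]
    half <- qnorm(0.975) * sqrt(p * (1 - p) / ph$n[i])
    expect_lt(abs(ph$p_hat[i] - p), half + 1e-12,
              label = paste("phase", ph$phase[i], "deviation"))
  }
})
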