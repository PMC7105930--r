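#' Reporting-behaviour parameters for the cohort simulator
#'
#' Defaults encode the three-phase engagement pattern seen in prescribed
#' e-diary monitoring: near-complete reporting in the first days, a long
#' fluctuating plateau, then a slow decline. `p_phase_a/b/c` are cohort-mean
#' daily reporting probabilities for reporting-day indices 1-`phase_a_len`,
#' the next `phase_b_len` days, and the remainder. `persistence` is the
#' standard deviation of a patient-level random effect on the logit reporting
#' probability; it is mean-preserving (the cohort mean of each phase stays at
#' the configured value whatever the heterogeneity). `postpone_coupling` ties
#' postponement to the same random effect, so lapse-prone patients postpone
#' more.
#'
#' @param p_phase_a,p_phase_b,p_phase_c Phase-mean daily reporting
#'   probabilities (defaults 0.931, 0.8365, 0.7855).
#' @param phase_a_len,phase_b_len Phase lengths in reporting days (6 and 40).
#' @param p_postpone Baseline probability that a reported day is entered the
#'   next day.
#' @param delayed_start_mean,advanced_end_mean Geometric means (days) of the
#'   delayed reporting start and the intended advanced reporting end.
#' @param persistence SD (logit scale) of the per-patient reporting random
#'   effect; 0 = fully homogeneous cohort.
#' @param postpone_coupling How strongly low reporting propensity raises the
#'   postponement probability (logit slope on the shared random effect).
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(p_phase_a = 0.931, p_phase_b = 0.8365, p_phase_c = 0.7855,
                            phase_a_len = 6L, phase_b_len = 40L,
                            p_postpone = 0.15,
                            delayed_start_mean = 2, advanced_end_mean = 3,
                            persistence = 1.5, postpone_coupling = 1) {
  probs <- c(p_phase_a, p_phase_b, p_phase_c, p_postpone)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (phase_a_len < 0 || phase_b_len < 0) abort("phase lengths must be >= 0")
  if (delayed_start_mean < 0 || advanced_end_mean < 0 || persistence < 0) {
    abort("means and persistence must be >= 0")
  }
  structure(
    list(
      p_phase_a = p_phase_a, p_phase_b = p_phase_b, p_phase_c = p_phase_c,
      phase_a_len = as.integer(phase_a_len), phase_b_len = as.integer(phase_b_len),
      p_postpone = p_postpone,
      delayed_start_mean = delayed_start_mean,
      advanced_end_mean = advanced_end_mean,
      persistence = persistence, postpone_coupling = postpone_coupling
    ),
    class = "behavior_params"
  )
}

#' Pollen-season parameters for the simulator
#'
#' A grass season modelled as one or two Gaussian-shaped peaks over a fixed
#' span with multiplicative lognormal day-to-day noise. Defaults give a main
#' peak of 199 grains/m^3 in late May with a smaller secondary June peak — a
#' realistic Mediterranean grass season magnitude and shape.
#'
#' @param start,end Season span (default March 1 to September 30).
#' @param peak_day Date of the main peak.
#' @param peak_height Main peak concentration, grains/m^3.
#' @param width_days Gaussian SD of the main peak, days.
#' @param second_peak Optional `list(day =, height =, width_days =)` for a
#'   secondary peak; `NULL` for a unimodal season.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (0 = deterministic curve).
#' @return A list of class `season_params`.
#' @export
season_params <- function(start = "2016-03-01", end = "2016-09-30",
                          peak_day = "2016-05-20", peak_height = 199,
                          width_days = 14,
                          second_peak = list(day = "2016-06-15", height = 90,
                                             width_days = 10),
                          noise_cv = 0.5) {
  if (peak_height < 0 || width_days <= 0 || noise_cv < 0) {
    abort("peak_height >= 0, width_days > 0 and noise_cv >= 0 required")
  }
  structure(
    list(
      start = as.Date(start), end = as.Date(end),
      peak_day = as.Date(peak_day), peak_height = peak_height,
      width_days = width_days, second_peak = second_peak, noise_cv = noise_cv
    ),
    class = "season_params"
  )
}

#' Prescription-window policy for the simulator
#'
#' Windows of 50-90 days (uniform), centred near the season peak with a
#' uniform jitter, emulating doctor-assigned monitoring intervals.
#'
#' @param min_duration,max_duration Window duration bounds, days.
#' @param start_jitter Max absolute jitter (days) of the window centre around
#'   the season peak.
#' @return A list of class `prescription_policy`.
#' @export
prescription_policy <- function(min_duration = 50L, max_duration = 90L,
                                start_jitter = 14L) {
  if (min_duration < 1 || max_duration < min_duration) {
    abort("require 1 <= min_duration <= max_duration")
  }
  structure(
    list(min_duration = as.integer(min_duration),
         max_duration = as.integer(max_duration),
         start_jitter = as.integer(start_jitter)),
    class = "prescription_policy"
  )
}

# Location mu such that E[plogis(mu + sd * Z)] = p for Z ~ N(0,1);
# mean-preserving logit-normal random effect. Quadrature on a fine grid.
logit_mean_offset <- function(p, sd) {
  if (p <= 0) return(-Inf)
  if (p >= 1) return(Inf)
  if (sd == 0) return(qlogis(p))
  z <- seq(-8, 8, length.out = 201)
  w <- dnorm(z)
  w <- w / sum(w)
  f <- function(mu) sum(w * plogis(mu + sd * z)) - p
  uniroot(f, lower = qlogis(p) - 8 * sd, upper = qlogis(p) + 8 * sd,
          tol = 1e-10)$root
}

#' Simulate a daily pollen-count series
#'
#' Daily concentrations are the sum of the configured Gaussian peaks times
#' multiplicative lognormal noise with unit mean and the configured
#' coefficient of variation, truncated at zero.
#'
#' @param season A [season_params()] object.
#' @param seed Optional integer seed (reproducible; the caller's RNG state is
#'   untouched).
#' @return A pollen-series tibble (see [pollen_series()]).
#' @export
simulate_pollen <- function(season = season_params(), seed = NULL) {
  run <- function() {
    dates <- seq(season$start, season$end, by = "day")
    t <- as.numeric(dates)
    mu <- season$peak_height *
      exp(-0.5 * ((t - as.numeric(season$peak_day)) / season$width_days)^2)
    if (!is.null(season$second_peak)) {
      sp <- season$second_peak
      mu <- mu + sp$height *
        exp(-0.5 * ((t - as.numeric(as.Date(sp$day))) / sp$width_days)^2)
    }
    if (season$noise_cv > 0) {
      sdlog <- sqrt(log(1 + season$noise_cv^2))
      noise <- rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      mu <- mu * noise
    }
    pollen_series(dates, pmax(0, mu), taxon = "grass", station_id = "synthetic")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Ordinal dose-response cut-points on the logit scale; with slope 1 on
# log(1 + concentration) the modal severity at 50 grains/m^3 is "moderate".
SEVERITY_CUTPOINTS <- c(2.2, 3.3, 5.2)

#' Simulate one patient's diary
#'
#' Draws a delayed start (geometric), reports the first active day (which
#' realises the reporting start), then reports each subsequent active day with
#' the phase- and patient-specific probability; the intended end is the
#' prescription end minus a geometric advanced end. Reported days are
#' postponed (entered next day) with the patient's postponement probability.
#' Symptom severities follow an ordinal-logit dose-response in
#' log(1 + concentration) with a patient sensitivity intercept; medication
#' intake is drawn conditional on the daily symptom level; VAS is a noisy
#' monotone rescaling of RTSS.
#'
#' @param behavior A [behavior_params()] object.
#' @param window A one-row prescription-window tibble.
#' @param series A pollen-series tibble supplying daily concentrations.
#' @param seed Optional integer seed.
#' @return A diary tibble (possibly re-ordered by day).
#' @export
simulate_patient <- function(behavior, window, series, seed = NULL) {
  run <- function() {
    stopifnot(nrow(window) == 1)
    b <- behavior
    dur <- window$duration

    u <- rnorm(1, 0, b$persistence)
    sens <- rnorm(1, 0, 0.5)
    p_post <- plogis(qlogis(b$p_postpone) - b$postpone_coupling * u)
    if (b$p_postpone == 0) p_post <- 0
    if (b$p_postpone == 1) p_post <- 1

    delayed <- min(rgeom(1, 1 / (1 + b$delayed_start_mean)), dur - 1L)
    advanced <- min(rgeom(1, 1 / (1 + b$advanced_end_mean)), dur - 1L - delayed)
    active <- seq(window$start + delayed, window$end - advanced, by = "day")
    m <- length(active)

    idx <- seq_len(m)
    phase_p <- c(b$p_phase_a, b$p_phase_b, b$p_phase_c)
    phase_of <- findInterval(idx, c(1, b$phase_a_len + 1, b$phase_a_len + b$phase_b_len + 1))
    mu_phase <- vapply(phase_p, logit_mean_offset, numeric(1), sd = b$persistence)
    p_day <- plogis(mu_phase[phase_of] + u)
    p_day[!is.finite(mu_phase[phase_of])] <- phase_p[phase_of][!is.finite(mu_phase[phase_of])]

    reported <- rbinom(m, 1, p_day) == 1
    reported[1] <- TRUE  # first active day defines the reporting start
    days <- active[reported]
    k <- length(days)

    conc <- series$concentration[match(days, series$date)]
    conc[is.na(conc)] <- 0
    eta <- log1p(conc) + sens
    lat <- matrix(rlogis(k * 6, location = rep(eta, 6)), nrow = k)
    sev <- matrix(0L, nrow = k, ncol = 6)
    for (cp in SEVERITY_CUTPOINTS) sev <- sev + (lat > cp)
    colnames(sev) <- SYMPTOM_COLS

    dss <- rowMeans(sev)
    anti <- rbinom(k, 1, plogis(-2 + 1.5 * dss))
    loc <- as.integer(dss >= 2) * rbinom(k, 1, 0.3)
    sys <- as.integer(dss >= 2) * rbinom(k, 1, 0.05)
    rtss <- rowSums(sev)
    vas <- pmin(10, pmax(0, 10 * rtss / 18 + rnorm(k, 0, 0.8)))
    postponed <- rbinom(k, 1, p_post)

    out <- tibble(
      patient_id = window$patient_id,
      day = days,
      entry_day = days + postponed
    )
    out <- bind_cols(out, as_tibble(sev))
    out$antihistamine <- anti
    out$local_corticosteroid <- loc
    out$systemic_corticosteroid <- sys
    out$vas <- vas
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a monitored cohort
#'
#' Generates one pollen season and `n` patients: prescription windows under
#' the policy, then each patient's diary under the behaviour model. All
#' randomness is governed by `seed`; identical seeds give identical cohorts.
#'
#' @param n Number of patients.
#' @param behavior A [behavior_params()] object.
#' @param season A [season_params()] object.
#' @param policy A [prescription_policy()] object.
#' @param seed Optional integer seed.
#' @return A list of class `cohort_sim`: `diary`, `prescriptions`, `pollen`
#'   tibbles and `params` (the ground truth used).
#' @export
simulate_cohort <- function(n, behavior = behavior_params(),
                            season = season_params(),
                            policy = prescription_policy(), seed = NULL) {
  if (n < 1) abort("n must be >= 1")
  run <- function() {
    pollen <- simulate_pollen(season, seed = NULL)
    ids <- sprintf("P%04d", seq_len(n))
    # sample from the explicit vectors (sample() on a scalar would expand it)
    resample <- function(v, n) v[sample.int(length(v), n, replace = TRUE)]
    dur <- resample(seq(policy$min_duration, policy$max_duration), n)
    jit <- resample(seq(-policy$start_jitter, policy$start_jitter), n)
    center <- season$peak_day + jit
    start <- center - dur %/% 2L
    windows <- prescription_window(ids, start, start + dur - 1L)
    diary <- map_dfr(seq_len(n), function(i) {
      simulate_patient(behavior, windows[i, ], pollen, seed = NULL)
    })
    structure(
      list(
        diary = diary, prescriptions = windows, pollen = pollen,
        params = list(behavior = unclass(behavior), season = NULL,
                      policy = unclass(policy), n = n, seed = seed)
      ),
      class = "cohort_sim"
    )
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out$params$season <- list(
    start = format(season$start), end = format(season$end),
    peak_day = format(season$peak_day), peak_height = season$peak_height,
    width_days = season$width_days, second_peak = season$second_peak,
    noise_cv = season$noise_cv
  )
  out
}

#' Write a simulated cohort to CSV files
#'
#' Emits `diary.csv`, `prescriptions.csv` and `pollen.csv` in the dialects the
#' package readers consume, plus `ground_truth.json` recording the generator
#' parameters (for parameter-recovery checks).
#'
#' @inheritParams simulate_cohort
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the four file paths and the `cohort_sim`.
#' @export
generate_cohort <- function(dir, n, behavior = behavior_params(),
                            season = season_params(),
                            policy = prescription_policy(), seed = NULL) {
  sim <- simulate_cohort(n, behavior, season, policy, seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    diary = file.path(dir, "diary.csv"),
    prescriptions = file.path(dir, "prescriptions.csv"),
    pollen = file.path(dir, "pollen.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  readr::write_csv(sim$diary, paths$diary)
  readr::write_csv(sim$prescriptions, paths$prescriptions)
  readr::write_csv(sim$pollen, paths$pollen)
  jsonlite::write_json(sim$params, paths$ground_truth, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, list(sim = sim)))
}
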