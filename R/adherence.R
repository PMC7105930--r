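#' Per-patient reporting summary and adherence ratios
#'
#' Decomposes each patient's prescription window the standard way: the
#' *reporting period* runs from the first to the last day actually reported
#' (inclusive); days before it inside the prescription are the *delayed
#' reporting start*, days after it the *advanced reporting end*; unreported
#' days inside the reporting period are *missing reporting days*. Entries made
#' the day after the day they refer to are *postponed*. The three ratios are
#'
#' * adherence = reporting days / reporting period x 100,
#' * adherence to prescription = reporting days / prescription period x 100,
#' * postponed reporting = postponed days / reporting days x 100.
#'
#' Patients may report outside their prescription window; such days still
#' anchor the reporting period (behaviour is what it is) while delayed start
#' and advanced end floor at zero.
#'
#' @param records A cleaned diary tibble (see [validate_records()]).
#' @param windows A prescription-window tibble; every patient in `records`
#'   must appear here, and every window patient gets a summary row (zeros and
#'   `no_reports = TRUE` if they never reported).
#' @return A tibble, one row per window patient: prescription bounds and
#'   duration, reporting bounds, `reporting_period_days`, `reporting_days`,
#'   `missing_days`, `delayed_start_days`, `advanced_end_days`,
#'   `postponed_days`, the three percentage ratios, and `no_reports`.
#' @export
summarize_reporting <- function(records, windows) {
  if (nrow(records) > 0) {
    check_diary(records)
    unknown <- setdiff(unique(records$patient_id), windows$patient_id)
    if (length(unknown) > 0) {
      abort(paste0(
        "records belong to patients without a prescription window: ",
        paste(unknown, collapse = ", ")
      ))
    }
  }

  per_patient <- if (nrow(records) > 0) {
    records %>%
      group_by(.data$patient_id) %>%
      summarise(
        reporting_start = min(.data$day),
        reporting_end = max(.data$day),
        reporting_days = n_distinct(.data$day),
        postponed_days = sum(as.integer(.data$entry_day - .data$day) == 1L),
        .groups = "drop"
      )
  } else {
    tibble(
      patient_id = character(), reporting_start = as.Date(character()),
      reporting_end = as.Date(character()), reporting_days = integer(),
      postponed_days = integer()
    )
  }

  windows %>%
    rename(prescription_start = "start", prescription_end = "end",
           prescription_days = "duration") %>%
    left_join(per_patient, by = "patient_id") %>%
    mutate(
      no_reports = is.na(.data$reporting_days),
      reporting_days = ifelse(.data$no_reports, 0L, .data$reporting_days),
      postponed_days = ifelse(.data$no_reports, 0L, .data$postponed_days),
      reporting_period_days = ifelse(
        .data$no_reports, 0L,
        as.integer(.data$reporting_end - .data$reporting_start) + 1L
      ),
      missing_days = .data$reporting_period_days - .data$reporting_days,
      delayed_start_days = ifelse(
        .data$no_reports, 0L,
        pmax(0L, as.integer(.data$reporting_start - .data$prescription_start))
      ),
      advanced_end_days = ifelse(
        .data$no_reports, 0L,
        pmax(0L, as.integer(.data$prescription_end - .data$reporting_end))
      ),
      adherence_pct = ifelse(
        .data$reporting_period_days > 0,
        .data$reporting_days / .data$reporting_period_days * 100, 0
      ),
      adherence_to_prescription_pct =
        ifelse(.data$prescription_days > 0,
               .data$reporting_days / .data$prescription_days * 100, 0),
      postponed_pct = ifelse(
        .data$reporting_days > 0,
        .data$postponed_days / .data$reporting_days * 100, 0
      )
    ) %>%
    select(
      "patient_id", "prescription_start", "prescription_end", "prescription_days",
      "reporting_start", "reporting_end", "reporting_period_days",
      "reporting_days", "missing_days", "delayed_start_days",
      "advanced_end_days", "postponed_days", "adherence_pct",
      "adherence_to_prescription_pct", "postponed_pct", "no_reports"
    )
}

#' Adherence restricted to a pollen period
#'
#' Adherence computed over the days lying both in the patient's reporting
#' period (default; or prescription period via `scope`) and in the pollen
#' period's intervals: reported such days / all such days x 100. Patients
#' whose restriction is empty get `NA` with `defined = FALSE` and are excluded
#' from cohort means downstream.
#'
#' @inheritParams summarize_reporting
#' @param period A `pollen_period` object (see [detect_periods()]).
#' @param scope Restrict within the `"reporting"` (default) or
#'   `"prescription"` period.
#' @return A tibble: `patient_id`, `days_in_period`, `reported_in_period`,
#'   `adherence_pct`, `defined`.
#' @export
period_adherence <- function(records, windows, period,
                             scope = c("reporting", "prescription")) {
  scope <- match.arg(scope)
  stopifnot(inherits(period, "pollen_period"))
  summ <- summarize_reporting(records, windows)

  one <- function(pid) {
    s <- summ[summ$patient_id == pid, ]
    if (scope == "reporting") {
      if (s$no_reports) {
        return(tibble(patient_id = pid, days_in_period = 0L,
                      reported_in_period = 0L, adherence_pct = NA_real_,
                      defined = FALSE))
      }
      span <- seq(s$reporting_start, s$reporting_end, by = "day")
    } else {
      span <- seq(s$prescription_start, s$prescription_end, by = "day")
    }
    in_period <- restrict_to_period(span, period)
    reported <- unique(records$day[records$patient_id == pid])
    n_den <- length(in_period)
    n_num <- sum(in_period %in% reported)
    tibble(
      patient_id = pid, days_in_period = n_den, reported_in_period = n_num,
      adherence_pct = if (n_den > 0) n_num / n_den * 100 else NA_real_,
      defined = n_den > 0
    )
  }
  map_dfr(summ$patient_id, one)
}

#' Alert and phone-call days for lapsed reporting
#'
#' Scans each prescription window day by day: a run of unreported days
#' triggers an automatic alert message when it reaches 2 consecutive days and
#' a phone call when it reaches 4; any reported day resets the run.
#'
#' @inheritParams summarize_reporting
#' @return A tibble: `patient_id`, `date`, `event` (`"alert"` or
#'   `"phone_call"`). Zero rows if nobody lapses.
#' @export
alert_days <- function(records, windows) {
  if (nrow(records) > 0) check_diary(records)
  one <- function(i) {
    w <- windows[i, ]
    days <- seq(w$start, w$end, by = "day")
    reported <- unique(records$day[records$patient_id == w$patient_id])
    run <- 0L
    out <- list()
    for (d in seq_along(days)) {
      if (days[d] %in% reported) {
        run <- 0L
      } else {
        run <- run + 1L
        if (run == 2L) out[[length(out) + 1L]] <- tibble(
          patient_id = w$patient_id, date = days[d], event = "alert")
        if (run == 4L) out[[length(out) + 1L]] <- tibble(
          patient_id = w$patient_id, date = days[d], event = "phone_call")
      }
    }
    bind_rows(out)
  }
  res <- map_dfr(seq_len(nrow(windows)), one)
  if (nrow(res) == 0) {
    res <- tibble(patient_id = character(), date = as.Date(character()),
                  event = character())
  }
  res
}

#' Per-day reporting flags indexed from each patient's reporting start
#'
#' Expands each reporting period into one row per day with a 1-based
#' reporting-day index and a reported/missing flag — the long format behind
#' the adherence trajectory and the early-window predictor.
#'
#' @inheritParams summarize_reporting
#' @return A tibble: `patient_id`, `index`, `date`, `reported`. Patients with
#'   no reports contribute no rows.
#' @export
reporting_flags <- function(records, windows) {
  summ <- summarize_reporting(records, windows)
  summ <- summ[!summ$no_reports, ]
  map_dfr(seq_len(nrow(summ)), function(i) {
    s <- summ[i, ]
    days <- seq(s$reporting_start, s$reporting_end, by = "day")
    reported <- unique(records$day[records$patient_id == s$patient_id])
    tibble(
      patient_id = s$patient_id,
      index = seq_along(days),
      date = days,
      reported = days %in% reported
    )
  })
}

#' Cohort adherence trajectory by reporting day
#'
#' For each reporting-day index t (1-based from each patient's first reported
#' day), the percentage of patients reporting at t among those whose reporting
#' period still covers t. Denominators shrink as reporting periods end; the
#' trajectory stops at the longest period. Indices are annotated with the
#' three adherence phases: A (initial high adherence), B (fluctuating
#' plateau), C (slow decline).
#'
#' @inheritParams summarize_reporting
#' @param phase_a_len Length of phase A in reporting days (default 6).
#' @param phase_b_len Length of phase B (default 40, so phase C starts at
#'   index 47).
#' @return A tibble: `index`, `n_at_risk`, `n_reported`, `pct`, `phase`.
#' @export
adherence_by_reporting_day <- function(records, windows,
                                       phase_a_len = 6L, phase_b_len = 40L) {
  flags <- reporting_flags(records, windows)
  if (nrow(flags) == 0) {
    return(tibble(index = integer(), n_at_risk = integer(),
                  n_reported = integer(), pct = numeric(), phase = character()))
  }
  flags %>%
    group_by(.data$index) %>%
    summarise(
      n_at_risk = n(),
      n_reported = sum(.data$reported),
      pct = .data$n_reported / .data$n_at_risk * 100,
      .groups = "drop"
    ) %>%
    mutate(phase = case_when(
      .data$index <= phase_a_len ~ "A",
      .data$index <= phase_a_len + phase_b_len ~ "B",
      TRUE ~ "C"
    ))
}

#' Adherence within a reporting-day index window
#'
#' Per-patient adherence over reporting-day indices `[lo, hi]` — e.g. the
#' second and third week of recording (`lo = 7`, `hi = 21`), used as an early
#' predictor of total adherence. Patients whose reporting period ends before
#' `hi` are excluded by default (`complete = FALSE`); with
#' `incomplete = "prorate"` their adherence is computed over the indices they
#' have.
#'
#' @inheritParams summarize_reporting
#' @param lo,hi First and last reporting-day index of the window (inclusive);
#'   `hi = Inf` means "to the end of each reporting period".
#' @param incomplete Handling of patients whose period ends inside the window.
#' @return A tibble: `patient_id`, `n_days`, `n_reported`,
#'   `window_adherence_pct`, `complete`.
#' @export
window_adherence <- function(records, windows, lo = 7, hi = 21,
                             incomplete = c("exclude", "prorate")) {
  incomplete <- match.arg(incomplete)
  flags <- reporting_flags(records, windows)
  out <- flags %>%
    filter(.data$index >= lo, .data$index <= hi) %>%
    group_by(.data$patient_id) %>%
    summarise(
      n_days = n(),
      n_reported = sum(.data$reported),
      complete = is.infinite(hi) | .data$n_days == (hi - lo + 1),
      .groups = "drop"
    ) %>%
    mutate(window_adherence_pct = .data$n_reported / .data$n_days * 100)
  if (incomplete == "exclude") out <- filter(out, .data$complete)
  select(out, "patient_id", "n_days", "n_reported", "window_adherence_pct", "complete")
}
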