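# Fixtures and independent oracles used across the suite.

# The worked monitoring example: a 54-day prescription, reporting starting
# 6 days late and ending 5 days early (43-day reporting period), with 7
# missing days inside the span, hence 36 reporting days.
fig1_cohort <- function() {
  window <- prescription_window("F1", "2016-04-01", "2016-05-24") # 54 days
  stopifnot(window$duration == 54L)
  rep_days <- seq(as.Date("2016-04-07"), as.Date("2016-05-19"), by = "day")
  stopifnot(length(rep_days) == 43L)
  missing_idx <- c(5L, 9L, 14L, 20L, 21L, 30L, 38L) # interior days only
  reported <- rep_days[-missing_idx]
  list(records = diary_record("F1", reported), window = window)
}

# Random valid diary rows for property tests.
random_records <- function(n, patient = "R1", start = as.Date("2016-05-01"),
                           meds = TRUE) {
  diary_record(
    patient, start + seq_len(n) - 1,
    entry_day = start + seq_len(n) - 1 + rbinom(n, 1, 0.3),
    sneezing = sample(0:3, n, TRUE), rhinorrhea = sample(0:3, n, TRUE),
    nasal_pruritus = sample(0:3, n, TRUE), nasal_congestion = sample(0:3, n, TRUE),
    itchy_eyes = sample(0:3, n, TRUE), watery_eyes = sample(0:3, n, TRUE),
    antihistamine = if (meds) rbinom(n, 1, 0.3) else 0L,
    local_corticosteroid = if (meds) rbinom(n, 1, 0.2) else 0L,
    systemic_corticosteroid = if (meds) rbinom(n, 1, 0.1) else 0L,
    vas = round(runif(n, 0, 10), 1)
  )
}

# A diary where the given patient reports exactly the given dates (all zeros).
# Accepts the numeric vectors base::setdiff() makes out of Dates.
reports_on <- function(patient, dates) {
  if (is.numeric(dates)) dates <- as.Date(dates, origin = "1970-01-01")
  diary_record(patient, as.Date(dates))
}

# Independent brute-force pollen-period classifier: enumerates every window
# explicitly with plain loops and marks in-period days; intervals via rle.
brute_inperiod <- function(x, spec, convention = "coverage",
                           sum_scope = "qualifying") {
  n <- length(x)
  L <- spec$window_len
  inp <- rep(FALSE, n)
  if (n >= L) {
    for (i in seq_len(n - L + 1)) {
      idx <- i:(i + L - 1)
      w <- x[idx]
      qual <- w >= spec$day_threshold
      ok <- if (spec$consecutive_required) {
        r <- rle(qual)
        any(r$lengths[r$values] >= spec$min_qualifying_days)
      } else {
        sum(qual) >= spec$min_qualifying_days
      }
      if (ok && !is.na(spec$window_sum_threshold)) {
        s <- if (sum_scope == "qualifying") sum(w[qual]) else sum(w)
        ok <- s >= spec$window_sum_threshold
      }
      if (ok) {
        if (convention == "coverage") inp[idx] <- TRUE else inp[idx[qual]] <- TRUE
      }
    }
  }
  inp
}

brute_intervals <- function(inp) {
  r <- rle(inp)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  data.frame(beg = begs[r$values], end = ends[r$values])
}

# In-period day mask implied by a detect_periods() result.
period_mask <- function(series, period) {
  dates <- series$date
  mask <- rep(FALSE, length(dates))
  if (period$n_intervals > 0) {
    for (i in seq_len(nrow(period$intervals))) {
      mask <- mask | (dates >= period$intervals$start[i] &
                        dates <= period$intervals$end[i])
    }
  }
  mask
}

# Random concentration series exercising thresholds 3/10/50 and zero runs.
random_concentrations <- function(n) {
  base <- sample(c(0, 1, 2, 3, 5, 9, 10, 20, 49, 50, 60, 120), n, replace = TRUE)
  base * rbinom(n, 1, 0.8)
}
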