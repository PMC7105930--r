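#' Build a daily pollen-count series
#'
#' One row per consecutive calendar day: dates must have no gaps (see
#' [read_pollen()] for an explicit zero-fill option when reading files).
#'
#' @param date Consecutive calendar dates (`Date` or ISO-8601 strings).
#' @param concentration Non-negative daily concentrations, grains/m^3.
#' @param taxon Pollen taxon label (default `"grass"`).
#' @param station_id Monitoring station label.
#' @return A tibble with columns `station_id`, `taxon`, `date`, `concentration`.
#' @examples
#' pollen_series(seq(as.Date("2016-05-01"), by = 1, length.out = 5), c(0, 4, 60, 55, 2))
#' @export
pollen_series <- function(date, concentration, taxon = "grass", station_id = "station") {
  out <- tibble(
    station_id = as.character(station_id),
    taxon = as.character(taxon),
    date = as.Date(date),
    concentration = as.numeric(concentration)
  )
  check_pollen_series(out)
  out
}

check_pollen_series <- function(series) {
  need <- c("date", "concentration")
  missing <- setdiff(need, names(series))
  if (length(missing) > 0) {
    abort(paste0("pollen series is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(series) < 1) abort("pollen series must contain at least one day")
  if (any(is.na(series$concentration)) || any(series$concentration < 0)) {
    abort("pollen concentrations must be non-negative")
  }
  d <- as.integer(diff(series$date))
  if (length(d) > 0 && any(d != 1L)) {
    abort("pollen series dates must be strictly consecutive (no gaps); see read_pollen(zero_fill = TRUE)")
  }
  invisible(series)
}

#' Define a pollen-period criteria set
#'
#' A sliding-window rule: an interval of `window_len` consecutive days
#' qualifies when at least `min_qualifying_days` of them reach
#' `day_threshold` grains/m^3 (consecutively, if `consecutive_required`), and —
#' when `window_sum_threshold` is given — the summed concentration reaches it.
#'
#' @param name Criteria label.
#' @param window_len Window length, days.
#' @param min_qualifying_days Minimum days at/above `day_threshold`.
#' @param day_threshold Per-day concentration threshold, grains/m^3.
#' @param window_sum_threshold Optional summed-concentration threshold,
#'   grains/m^3 (`NA` for none).
#' @param consecutive_required Must the qualifying days be consecutive?
#' @return A one-row tibble.
#' @export
criteria_spec <- function(name, window_len, min_qualifying_days, day_threshold,
                          window_sum_threshold = NA_real_, consecutive_required = FALSE) {
  if (min_qualifying_days > window_len) {
    abort("min_qualifying_days cannot exceed window_len")
  }
  if (day_threshold <= 0 || (!is.na(window_sum_threshold) && window_sum_threshold <= 0)) {
    abort("thresholds must be positive")
  }
  tibble(
    name = as.character(name),
    window_len = as.integer(window_len),
    min_qualifying_days = as.integer(min_qualifying_days),
    day_threshold = as.numeric(day_threshold),
    window_sum_threshold = as.numeric(window_sum_threshold),
    consecutive_required = isTRUE(consecutive_required)
  )
}

#' The five built-in grass pollen-period criteria
#'
#' EAACI and locally adapted definitions of the whole season, peak season and
#' high pollen days for grass:
#'
#' * `eaaci_whole` — 5 days out of 7 consecutive, each >= 3 grains/m^3, sum >= 30;
#' * `local_whole` — 5 days out of 7 consecutive, each >= 10 grains/m^3, sum >= 100;
#' * `eaaci_peak` — 3 consecutive days, each >= 50 grains/m^3;
#' * `local_peak` — 3 days out of 5 consecutive, each >= 50 grains/m^3;
#' * `eaaci_high_days` — single days with >= 50 grains/m^3.
#'
#' @return A five-row criteria tibble (see [criteria_spec()]).
#' @export
builtin_criteria <- function() {
  bind_rows(
    criteria_spec("eaaci_whole", 7, 5, 3, 30),
    criteria_spec("local_whole", 7, 5, 10, 100),
    criteria_spec("eaaci_peak", 3, 3, 50, NA_real_, consecutive_required = TRUE),
    criteria_spec("local_peak", 5, 3, 50, NA_real_),
    criteria_spec("eaaci_high_days", 1, 1, 50, NA_real_)
  )
}

# Accept a criteria name or a one-row criteria tibble.
resolve_criteria <- function(criteria) {
  if (is.character(criteria) && length(criteria) == 1) {
    all <- builtin_criteria()
    if (!criteria %in% all$name) {
      abort(paste0(
        "unknown criteria '", criteria, "'; built-in criteria are: ",
        paste(all$name, collapse = ", ")
      ))
    }
    return(all[all$name == criteria, ])
  }
  if (is.data.frame(criteria) && nrow(criteria) == 1) return(as_tibble(criteria))
  abort("criteria must be a built-in criteria name or a one-row criteria tibble")
}

max_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Qualifying sliding windows of a pollen series
#'
#' Evaluates the criteria rule at every window start position.
#'
#' @param series A pollen-series tibble (see [pollen_series()]).
#' @param criteria A built-in criteria name or one-row criteria tibble.
#' @param sum_scope For criteria with a summed-concentration threshold: sum
#'   over the qualifying days only (`"qualifying"`, default) or over all days
#'   of the window (`"window"`).
#' @return Logical vector over window start positions, length
#'   `nrow(series) - window_len + 1` (length 0 if the series is shorter than
#'   the window).
#' @export
qualifying_windows <- function(series, criteria, sum_scope = c("qualifying", "window")) {
  check_pollen_series(series)
  spec <- resolve_criteria(criteria)
  sum_scope <- match.arg(sum_scope)
  x <- series$concentration
  L <- spec$window_len
  n <- length(x)
  if (n < L) return(logical(0))
  # stats::embed gives one row per window (columns in reverse day order,
  # immaterial for counts/sums; run lengths are reversal-invariant too)
  W <- stats::embed(x, L)
  if (L == 1) W <- matrix(x, ncol = 1)
  Q <- W >= spec$day_threshold
  if (spec$consecutive_required && spec$min_qualifying_days > 1) {
    ok <- apply(Q, 1, function(q) max_run(q) >= spec$min_qualifying_days)
  } else {
    ok <- rowSums(Q) >= spec$min_qualifying_days
  }
  if (!is.na(spec$window_sum_threshold)) {
    s <- if (sum_scope == "qualifying") rowSums(W * Q) else rowSums(W)
    ok <- ok & s >= spec$window_sum_threshold
  }
  unname(ok)
}

#' Detect pollen periods under a criteria set
#'
#' Marks in-period days and merges maximal runs of them into intervals. Two
#' day-marking conventions are supported:
#'
#' * `"coverage"` (default): every day covered by at least one qualifying
#'   window is in-period;
#' * `"qualifying_days"`: only days at/above the day threshold that lie inside
#'   a qualifying window are in-period.
#'
#' The conventions coincide for single-day criteria; for windowed criteria the
#' coverage convention yields longer, more merged periods. The choice changes
#' cumulative durations, so reports record which convention produced them.
#'
#' @inheritParams qualifying_windows
#' @param convention Day-marking convention, see Details.
#' @return An object of class `pollen_period`: criteria name, convention
#'   flags, an `intervals` tibble (`start`, `end`, `days`), `n_intervals` and
#'   `cumulative_days`. [tidy()] returns the intervals, [glance()] the
#'   one-row summary.
#' @examples
#' s <- pollen_series(seq(as.Date("2016-06-01"), by = 1, length.out = 11),
#'                    c(0, 0, 60, 60, 60, 0, 0, 60, 60, 60, 0))
#' detect_periods(s, "eaaci_peak")
#' @export
detect_periods <- function(series, criteria,
                           convention = c("coverage", "qualifying_days"),
                           sum_scope = c("qualifying", "window")) {
  check_pollen_series(series)
  spec <- resolve_criteria(criteria)
  convention <- match.arg(convention)
  sum_scope <- match.arg(sum_scope)
  n <- nrow(series)
  L <- spec$window_len
  ok <- qualifying_windows(series, spec, sum_scope = sum_scope)

  inp <- rep(FALSE, n)
  starts <- which(ok)
  if (length(starts) > 0) {
    # difference-array coverage count: covered[i] > 0 iff day i lies in a
    # qualifying window
    d <- integer(n + 1L)
    for (s in starts) {
      d[s] <- d[s] + 1L
      d[s + L] <- d[s + L] - 1L
    }
    covered <- cumsum(d[seq_len(n)]) > 0
    inp <- if (convention == "coverage") {
      covered
    } else {
      covered & series$concentration >= spec$day_threshold
    }
  }

  r <- rle(inp)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  keep <- r$values
  intervals <- tibble(
    start = series$date[begs[keep]],
    end = series$date[ends[keep]],
    days = r$lengths[keep]
  )
  structure(
    list(
      criteria = spec$name,
      convention = convention,
      sum_scope = sum_scope,
      intervals = intervals,
      n_intervals = nrow(intervals),
      cumulative_days = sum(intervals$days),
      series_start = min(series$date),
      series_end = max(series$date)
    ),
    class = "pollen_period"
  )
}

#' @export
print.pollen_period <- function(x, ...) {
  cat("<pollen_period> criteria:", x$criteria,
      sprintf("(%s convention)\n", x$convention))
  cat("  intervals:", x$n_intervals, " cumulative days:", x$cumulative_days, "\n")
  if (x$n_intervals > 0) {
    cat(paste0(
      "  ", format(x$intervals$start), " .. ", format(x$intervals$end),
      " (", x$intervals$days, "d)\n"
    ), sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pollen_period <- function(x, ...) {
  out <- x$intervals
  out$criteria <- rep(x$criteria, nrow(out))
  select(out, "criteria", "start", "end", "days")
}

#' @exportS3Method generics::glance
glance.pollen_period <- function(x, ...) {
  tibble(
    criteria = x$criteria, convention = x$convention, sum_scope = x$sum_scope,
    n_intervals = x$n_intervals, cumulative_days = x$cumulative_days
  )
}

#' Pollen-period report across criteria sets
#'
#' Runs [detect_periods()] for each criteria row and returns a season report
#' shaped like the standard published tables: one row per criteria with the
#' interval count, cumulative duration, and the interval list.
#'
#' @inheritParams detect_periods
#' @param criteria A criteria tibble (default [builtin_criteria()]).
#' @return A tibble with `criteria`, `n_intervals`, `cumulative_days`,
#'   `intervals` (list-column of interval tibbles), plus the convention flags.
#' @export
detect_all_periods <- function(series, criteria = builtin_criteria(),
                               convention = c("coverage", "qualifying_days"),
                               sum_scope = c("qualifying", "window")) {
  convention <- match.arg(convention)
  sum_scope <- match.arg(sum_scope)
  periods <- map(seq_len(nrow(criteria)), function(i) {
    detect_periods(series, criteria[i, ], convention = convention, sum_scope = sum_scope)
  })
  tibble(
    criteria = criteria$name,
    n_intervals = map_dbl(periods, "n_intervals"),
    cumulative_days = map_dbl(periods, "cumulative_days"),
    convention = convention,
    sum_scope = sum_scope,
    intervals = map(periods, "intervals"),
    period = periods
  )
}

#' Restrict dates to a pollen period
#'
#' @param dates A `Date` vector.
#' @param period A `pollen_period` object.
#' @return The subset of `dates` falling inside any interval of the period.
#' @export
restrict_to_period <- function(dates, period) {
  stopifnot(inherits(period, "pollen_period"))
  dates <- as.Date(dates)
  if (period$n_intervals == 0 || length(dates) == 0) return(dates[0])
  keep <- rep(FALSE, length(dates))
  for (i in seq_len(nrow(period$intervals))) {
    keep <- keep |
      (dates >= period$intervals$start[i] & dates <= period$intervals$end[i])
  }
  dates[keep]
}
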