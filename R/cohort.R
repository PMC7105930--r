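# Spearman rank correlation with midrank tie handling; flags degenerate
# (zero-variance) inputs rather than erroring.
spearman_cor <- function(x, y, n_excluded = 0L) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("insufficient data: need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n,
                  n_excluded = n_excluded, degenerate = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
         n_excluded = n_excluded, degenerate = FALSE)
}

#' Early-window prediction of total adherence
#'
#' Spearman rank correlation between each patient's adherence achieved in an
#' early window of reporting-day indices (default the 7th-21st, i.e. the
#' second and third recording week) and their total adherence over the whole
#' reporting period. A strong correlation means the first weeks of behaviour
#' predict overall engagement.
#'
#' @inheritParams window_adherence
#' @param incomplete Patients whose reporting period ends before `hi` are
#'   excluded (default) or pro-rated; see [window_adherence()].
#' @return A one-row tibble: `rho`, `p_value`, `n`, `n_excluded`,
#'   `degenerate`.
#' @export
early_window_correlation <- function(records, windows, lo = 7, hi = 21,
                                     incomplete = c("exclude", "prorate")) {
  incomplete <- match.arg(incomplete)
  ew <- window_adherence(records, windows, lo = lo, hi = hi, incomplete = incomplete)
  summ <- summarize_reporting(records, windows)
  summ <- summ[!summ$no_reports, ]
  dat <- inner_join(ew, summ[c("patient_id", "adherence_pct")], by = "patient_id")
  spearman_cor(dat$window_adherence_pct, dat$adherence_pct,
               n_excluded = nrow(summ) - nrow(dat))
}

#' Postponed reporting versus total adherence
#'
#' Spearman rank correlation between each patient's postponed-reporting
#' percentage and their total adherence. In monitored cohorts this is
#' typically negative: patients who often enter yesterday's record today are
#' also the ones who lapse.
#'
#' @param summaries A reporting summary tibble from [summarize_reporting()].
#' @return A one-row tibble: `rho`, `p_value`, `n`, `n_excluded`, `degenerate`.
#' @export
postponed_correlation <- function(summaries) {
  dat <- summaries[!summaries$no_reports, ]
  spearman_cor(dat$postponed_pct, dat$adherence_pct,
               n_excluded = sum(summaries$no_reports))
}

#' Compare adherence across pollen-period definitions
#'
#' Nonparametric Friedman test for repeated measures across K period
#' definitions, followed by all pairwise Wilcoxon signed-rank tests with
#' Bonferroni correction (adjusted p = min(1, raw p x number of comparisons)).
#' Patients with an undefined adherence under any definition are dropped and
#' counted.
#'
#' @param data A long tibble with one adherence value per patient per period
#'   definition.
#' @param patient_col,period_col,value_col Column names (strings) of the
#'   patient identifier, the period definition, and the adherence value.
#' @return An object of class `period_comparison`; [glance()] returns the
#'   Friedman statistic row, [tidy()] the pairwise table.
#' @export
compare_period_adherence <- function(data, patient_col = "patient_id",
                                     period_col = "period",
                                     value_col = "adherence_pct") {
  wide <- data %>%
    select(all_of(c(patient_col, period_col, value_col))) %>%
    tidyr::pivot_wider(names_from = all_of(period_col),
                       values_from = all_of(value_col))
  m <- as.matrix(wide[, -1, drop = FALSE])
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  k <- ncol(m)
  n <- nrow(m)
  if (k < 2 || n < 2) {
    abort("insufficient data: need >= 2 period definitions and >= 2 complete patients")
  }

  fr <- friedman.test(m)
  fr_stat <- unname(fr$statistic)
  fr_p <- fr$p.value
  if (!is.finite(fr_stat) && all(apply(m, 1, stats::sd) == 0)) {
    # no within-patient variation at all: no evidence of any difference
    fr_stat <- 0
    fr_p <- 1
  }
  pairs <- utils::combn(colnames(m), 2)
  n_comp <- ncol(pairs)
  pairwise <- map_dfr(seq_len(n_comp), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    if (all(m[, a] == m[, b])) {
      return(tibble(period1 = a, period2 = b, statistic = 0, p_value = 1))
    }
    wt <- suppressWarnings(wilcox.test(m[, a], m[, b], paired = TRUE, exact = FALSE))
    tibble(period1 = a, period2 = b,
           statistic = unname(wt$statistic),
           p_value = wt$p.value)
  })
  pairwise$p_adjusted <- pmin(1, pairwise$p_value * n_comp)

  structure(
    list(
      friedman = tibble(
        statistic = fr_stat,
        df = unname(fr$parameter),
        p_value = fr_p
      ),
      pairwise = pairwise,
      n = n, k = k, n_dropped = n_dropped,
      posthoc = "Wilcoxon signed-rank, Bonferroni-adjusted"
    ),
    class = "period_comparison"
  )
}

#' @export
print.period_comparison <- function(x, ...) {
  cat("Friedman repeated-measures comparison of adherence across",
      x$k, "period definitions\n")
  cat(sprintf("  n = %d patients (%d dropped with undefined cells)\n",
              x$n, x$n_dropped))
  cat(sprintf("  chi-squared = %.3f, df = %d, p = %s\n",
              x$friedman$statistic, x$friedman$df,
              format_pvalue(x$friedman$p_value)))
  cat("  post hoc:", x$posthoc, "\n")
  pw <- x$pairwise
  for (i in seq_len(nrow(pw))) {
    cat(sprintf("    %s vs %s: p(adj) = %s\n", pw$period1[i], pw$period2[i],
                format_pvalue(pw$p_adjusted[i])))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.period_comparison <- function(x, ...) x$pairwise

#' @exportS3Method generics::glance
glance.period_comparison <- function(x, ...) {
  bind_cols(x$friedman, tibble(n = x$n, k = x$k, n_dropped = x$n_dropped))
}

#' Mean daily score trajectories
#'
#' Per-calendar-date cohort means of VAS, RTSS and CSMS over the patients who
#' reported that day, optionally restricted to a pollen period (e.g. the local
#' whole season). Dates with no reports are gaps — they are simply absent, not
#' zeros.
#'
#' @param records A diary tibble.
#' @param period Optional `pollen_period` restricting the dates.
#' @return A tibble: `day`, `n`, `vas`, `rtss`, `csms` (means).
#' @export
score_trajectories <- function(records, period = NULL) {
  scored <- score_diary(records)
  if (!is.null(period)) {
    keep_dates <- restrict_to_period(unique(scored$day), period)
    scored <- filter(scored, .data$day %in% keep_dates)
  }
  scored %>%
    group_by(.data$day) %>%
    summarise(
      n = n(),
      vas = mean(.data$vas),
      rtss = mean(.data$rtss),
      csms = mean(.data$csms),
      .groups = "drop"
    ) %>%
    arrange(.data$day)
}
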