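#' Plot the cohort adherence trajectory
#'
#' Line plot of adherence percentage by reporting-day index with the three
#' engagement phases shaded.
#'
#' @param trajectory Output of [adherence_by_reporting_day()].
#' @param phase_a_len,phase_b_len Phase boundaries used for shading.
#' @return A ggplot object.
#' @export
plot_adherence_trajectory <- function(trajectory, phase_a_len = 6L, phase_b_len = 40L) {
  max_i <- max(trajectory$index)
  shading <- tibble(
    phase = c("A", "B", "C"),
    xmin = c(0.5, phase_a_len + 0.5, phase_a_len + phase_b_len + 0.5),
    xmax = c(phase_a_len + 0.5, phase_a_len + phase_b_len + 0.5, max_i + 0.5)
  )
  shading <- shading[shading$xmin < shading$xmax, ]
  ggplot2::ggplot(trajectory, ggplot2::aes(x = .data$index, y = .data$pct)) +
    ggplot2::geom_rect(
      data = shading,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, fill = .data$phase),
      ymin = -Inf, ymax = Inf, alpha = 0.15, inherit.aes = FALSE
    ) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "Phase") +
    ggplot2::labs(x = "Reporting day", y = "Adherence (%)") +
    ggplot2::theme_minimal()
}

#' Plot mean daily score trajectories
#'
#' VAS, RTSS and CSMS cohort means by calendar date, each on its own panel
#' (the scores have different ranges).
#'
#' @param scores Output of [score_trajectories()].
#' @return A ggplot object.
#' @export
plot_score_trajectories <- function(scores) {
  long <- tidyr::pivot_longer(scores, c("vas", "rtss", "csms"),
                              names_to = "score", values_to = "mean")
  long$score <- factor(toupper(long$score), levels = c("VAS", "RTSS", "CSMS"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$mean)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~score, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Cohort mean") +
    ggplot2::theme_minimal()
}

#' Plot mean adherence by pollen-period definition
#'
#' Point-and-interval plot (mean with normal-approximation 95% CI) of
#' per-patient adherence for the total reporting period and each pollen-period
#' definition.
#'
#' @param adherence_long A long tibble with columns `period` and
#'   `adherence_pct` (one row per patient per definition), e.g. the
#'   `adherence_long` element of [run_pipeline()]'s bundle.
#' @return A ggplot object.
#' @export
plot_period_adherence <- function(adherence_long) {
  summ <- adherence_long %>%
    filter(!is.na(.data$adherence_pct)) %>%
    group_by(.data$period) %>%
    summarise(
      mean = mean(.data$adherence_pct),
      se = stats::sd(.data$adherence_pct) / sqrt(n()),
      .groups = "drop"
    ) %>%
    mutate(lo = .data$mean - qnorm(0.975) * .data$se,
           hi = .data$mean + qnorm(0.975) * .data$se)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$period, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::labs(x = NULL, y = "Mean adherence (%, 95% CI)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Scatter plot for an adherence correlation
#'
#' Early-window (or postponed) percentage against total adherence with the
#' Spearman rho annotated.
#'
#' @param data A tibble with the two percentage columns.
#' @param x,y Column names (strings) to plot.
#' @param cor_row Optional one-row correlation tibble (from
#'   [early_window_correlation()] or [postponed_correlation()]) to annotate.
#' @return A ggplot object.
#' @export
plot_adherence_correlation <- function(data, x, y, cor_row = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data[[x]], y = .data[[y]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::theme_minimal()
  if (!is.null(cor_row) && !isTRUE(cor_row$degenerate)) {
    p <- p + ggplot2::labs(
      subtitle = sprintf("Spearman rho = %.2f, p = %s",
                         cor_row$rho, format_pvalue(cor_row$p_value))
    )
  }
  p
}
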