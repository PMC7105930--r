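parse_date_col <- function(x, col, path) {
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x))
  if (length(bad) > 0) {
    abort(paste0(
      "unparsable ISO-8601 dates in column '", col, "' of ", path,
      " at data row(s): ", paste(head(bad, 10), collapse = ", ")
    ))
  }
  d
}

require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(path, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
}

#' Read an e-diary CSV
#'
#' Expects one row per record with columns `patient_id`, `day`, `entry_day`
#' (ISO-8601), the six severity columns, the three medication indicator
#' columns, and `vas`. Extra columns (e.g. lung symptoms, daily-activity
#' items) are passed through untouched.
#'
#' @param path CSV file path.
#' @return A validated diary tibble.
#' @export
read_diary <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_cols(df, DIARY_COLS, path)
  df$patient_id <- as.character(df$patient_id)
  df$day <- parse_date_col(df$day, "day", path)
  df$entry_day <- parse_date_col(df$entry_day, "entry_day", path)
  for (col in c(SYMPTOM_COLS, MEDICATION_COLS)) df[[col]] <- as.integer(df[[col]])
  df$vas <- as.numeric(df$vas)
  check_diary(df)
  df
}

#' Read a prescription-window CSV
#'
#' Expects columns `patient_id`, `start`, `end` (ISO-8601).
#'
#' @param path CSV file path.
#' @return A prescription-window tibble with `duration` added.
#' @export
read_prescriptions <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_cols(df, c("patient_id", "start", "end"), path)
  prescription_window(
    df$patient_id,
    parse_date_col(df$start, "start", path),
    parse_date_col(df$end, "end", path)
  )
}

#' Read a daily pollen-count CSV
#'
#' Expects columns `date` (ISO-8601) and `concentration` (grains/m^3), with
#' optional `taxon` and `station_id`. The series must be gap-free; with
#' `zero_fill = TRUE`, missing dates are filled with concentration 0 and a
#' warning lists how many were filled. Multi-taxon files are filtered with
#' `taxon`.
#'
#' @param path CSV file path.
#' @param taxon Taxon to keep if a `taxon` column is present (default
#'   `"grass"`; ignored otherwise).
#' @param zero_fill Fill missing dates with 0 instead of erroring.
#' @return A pollen-series tibble.
#' @export
read_pollen <- function(path, taxon = "grass", zero_fill = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_cols(df, c("date", "concentration"), path)
  if ("taxon" %in% names(df)) df <- df[df$taxon == taxon, , drop = FALSE]
  if (nrow(df) == 0) abort(paste0("no rows for taxon '", taxon, "' in ", path))
  df$date <- parse_date_col(df$date, "date", path)
  df <- df[order(df$date), , drop = FALSE]
  if (anyDuplicated(df$date)) abort(paste0("duplicated dates in ", path))
  gaps <- as.integer(diff(df$date))
  if (any(gaps != 1L)) {
    if (!zero_fill) {
      abort(paste0(
        "pollen series in ", path, " has ", sum(gaps - 1L),
        " missing day(s); re-read with zero_fill = TRUE to fill them with 0"
      ))
    }
    full <- tibble(date = seq(min(df$date), max(df$date), by = "day"))
    n_fill <- nrow(full) - nrow(df)
    df <- left_join(full, df, by = "date")
    df$concentration[is.na(df$concentration)] <- 0
    warn(paste0("zero-filled ", n_fill, " missing day(s) in ", path))
  }
  pollen_series(
    df$date, df$concentration,
    taxon = if ("taxon" %in% names(df)) {
      (df$taxon[!is.na(df$taxon)] %||% taxon)[1]
    } else taxon,
    station_id = if ("station_id" %in% names(df)) {
      (df$station_id[!is.na(df$station_id)] %||% "station")[1]
    } else "station"
  )
}

#' Configuration for the full analysis pipeline
#'
#' @param diary,prescriptions,pollen Input tibbles, or paths to the
#'   corresponding CSV files.
#' @param out_dir Output directory; `NULL` to skip writing files.
#' @param criteria Character vector of built-in criteria names to evaluate.
#' @param convention,sum_scope Period-detection conventions, see
#'   [detect_periods()].
#' @param phase_a_len,phase_b_len Trajectory phase boundaries, see
#'   [adherence_by_reporting_day()].
#' @param early_window Two reporting-day indices bounding the early predictor
#'   window.
#' @param score_season Criteria name whose period restricts the score
#'   trajectories.
#' @param alpha Significance level recorded in the report.
#' @param seed Seed recorded in the provenance output (the pipeline itself is
#'   deterministic).
#' @param zero_fill_pollen Zero-fill gapped pollen files, see [read_pollen()].
#' @param write_plots Also write trajectory/period figures (PDF) to `out_dir`.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(diary, prescriptions, pollen, out_dir = NULL,
                            criteria = builtin_criteria()$name,
                            convention = "coverage", sum_scope = "qualifying",
                            phase_a_len = 6L, phase_b_len = 40L,
                            early_window = c(7L, 21L),
                            score_season = "local_whole",
                            alpha = 0.05, seed = NULL,
                            zero_fill_pollen = FALSE, write_plots = FALSE) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  known <- builtin_criteria()$name
  bad <- setdiff(criteria, known)
  if (length(bad) > 0) {
    abort(paste0("unknown criteria name(s): ", paste(bad, collapse = ", ")))
  }
  if (!score_season %in% criteria) {
    abort("score_season must be one of the selected criteria")
  }
  structure(
    list(
      diary = diary, prescriptions = prescriptions, pollen = pollen,
      out_dir = out_dir, criteria = criteria,
      convention = match.arg(convention, c("coverage", "qualifying_days")),
      sum_scope = match.arg(sum_scope, c("qualifying", "window")),
      phase_a_len = as.integer(phase_a_len), phase_b_len = as.integer(phase_b_len),
      early_window = as.integer(early_window), score_season = score_season,
      alpha = alpha, seed = seed, zero_fill_pollen = zero_fill_pollen,
      write_plots = write_plots
    ),
    class = "run_config"
  )
}

load_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1) reader(x, ...) else as_tibble(x)
}

#' Run the full monitoring analysis pipeline
#'
#' simulate/read -> validate -> detect pollen periods -> per-patient adherence
#' -> cohort analysis -> report. Writes (when `out_dir` is set):
#' `patient_summaries.csv`, `pollen_periods.csv`, `period_adherence.csv`,
#' `trajectory.csv`, `score_trajectories.csv`, `analysis.json`, and
#' `run_info.json` recording every convention flag and the seed. Reruns with
#' the same inputs and config are numerically identical.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list bundle with all intermediate and final tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  diary <- load_input(config$diary, read_diary)
  windows <- load_input(config$prescriptions, read_prescriptions)
  pollen <- load_input(config$pollen, read_pollen, zero_fill = config$zero_fill_pollen)
  check_pollen_series(pollen)

  val <- validate_records(diary, windows)
  records <- val$records

  summaries <- summarize_reporting(records, windows)
  periods <- detect_all_periods(
    pollen, builtin_criteria()[builtin_criteria()$name %in% config$criteria, ],
    convention = config$convention, sum_scope = config$sum_scope
  )

  total_adh <- summaries %>%
    filter(!.data$no_reports) %>%
    transmute(.data$patient_id, period = "total", adherence_pct = .data$adherence_pct,
              defined = TRUE)
  per_period <- map_dfr(seq_len(nrow(periods)), function(i) {
    pa <- period_adherence(records, windows, periods$period[[i]])
    tibble(patient_id = pa$patient_id, period = periods$criteria[i],
           adherence_pct = pa$adherence_pct, defined = pa$defined)
  })
  adherence_long <- bind_rows(total_adh, per_period)

  comparison <- compare_period_adherence(
    filter(adherence_long, .data$period != "total")
  )
  trajectory <- adherence_by_reporting_day(
    records, windows,
    phase_a_len = config$phase_a_len, phase_b_len = config$phase_b_len
  )
  early <- early_window_correlation(
    records, windows, lo = config$early_window[1], hi = config$early_window[2]
  )
  postponed <- postponed_correlation(summaries)
  season_period <- periods$period[[which(periods$criteria == config$score_season)]]
  scores <- score_trajectories(records, season_period)
  alerts <- alert_days(records, windows)

  bundle <- list(
    records = records, issues = val$issues, summaries = summaries,
    periods = periods, adherence_long = adherence_long,
    comparison = comparison, trajectory = trajectory,
    early_window = early, postponed = postponed,
    score_trajectories = scores, alerts = alerts, config = config
  )

  if (!is.null(config$out_dir)) write_report_bundle(bundle, config)
  invisible(bundle)
}

write_report_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)

  readr::write_csv(bundle$summaries, p("patient_summaries.csv"))
  period_tbl <- bundle$periods %>%
    mutate(interval_list = map_chr(.data$intervals, function(iv) {
      paste(paste0(format(iv$start), "..", format(iv$end)), collapse = "; ")
    })) %>%
    select("criteria", "n_intervals", "cumulative_days", "convention",
           "sum_scope", "interval_list")
  readr::write_csv(period_tbl, p("pollen_periods.csv"))
  readr::write_csv(bundle$adherence_long, p("period_adherence.csv"))
  readr::write_csv(bundle$trajectory, p("trajectory.csv"))
  readr::write_csv(bundle$score_trajectories, p("score_trajectories.csv"))

  analysis <- list(
    early_window = as.list(bundle$early_window),
    postponed = as.list(bundle$postponed),
    friedman = as.list(glance(bundle$comparison)),
    pairwise = bundle$comparison$pairwise,
    pairwise_rendered = transmute(
      bundle$comparison$pairwise,
      pair = paste(.data$period1, "vs", .data$period2),
      p_adjusted = format_pvalue(.data$p_adjusted)
    ),
    alpha = config$alpha
  )
  jsonlite::write_json(analysis, p("analysis.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")

  run_info <- list(
    package = "pollendiary",
    version = as.character(utils::packageVersion("pollendiary")),
    seed = config$seed,
    criteria = config$criteria,
    convention = config$convention,
    sum_scope = config$sum_scope,
    phase_a_len = config$phase_a_len,
    phase_b_len = config$phase_b_len,
    early_window = config$early_window,
    score_season = config$score_season,
    alpha = config$alpha,
    zero_fill_pollen = config$zero_fill_pollen
  )
  jsonlite::write_json(run_info, p("run_info.json"), auto_unbox = TRUE, digits = NA)

  if (isTRUE(config$write_plots)) {
    save_plot <- function(file, plot, w = 7, h = 4.5) {
      grDevices::pdf(p(file), width = w, height = h)
      print(plot)
      grDevices::dev.off()
    }
    save_plot("fig_trajectory.pdf",
              plot_adherence_trajectory(bundle$trajectory,
                                        phase_a_len = config$phase_a_len,
                                        phase_b_len = config$phase_b_len))
    save_plot("fig_scores.pdf", plot_score_trajectories(bundle$score_trajectories))
    save_plot("fig_period_adherence.pdf",
              plot_period_adherence(bundle$adherence_long))
  }
  invisible(NULL)
}
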