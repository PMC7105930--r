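#' Build an e-diary tibble
#'
#' Constructs (and validates) a tibble of daily e-diary records, one row per
#' patient per monitored day. Each record carries the day it refers to
#' (`day`), the day it was actually entered (`entry_day`, same day or the
#' following one), six symptom severities on the 4-grade emoticon scale
#' (0 = none, 1 = mild, 2 = moderate, 3 = severe), three binary medication
#' intake indicators, and a 0-10 visual analog scale rating.
#'
#' @param patient_id Patient identifier(s).
#' @param day Calendar date(s) the record refers to (`Date` or ISO-8601 string).
#' @param entry_day Date(s) the record was entered; defaults to `day`.
#' @param sneezing,rhinorrhea,nasal_pruritus,nasal_congestion,itchy_eyes,watery_eyes
#'   Integer severities in `0:3`.
#' @param antihistamine,local_corticosteroid,systemic_corticosteroid Binary
#'   (0/1) intake indicators.
#' @param vas Visual analog scale rating in `[0, 10]`.
#'
#' @return A tibble with the standard diary columns.
#' @examples
#' diary_record("P001", "2016-05-10", sneezing = 2, itchy_eyes = 1, vas = 3.5)
#' @export
diary_record <- function(patient_id, day, entry_day = day,
                         sneezing = 0L, rhinorrhea = 0L, nasal_pruritus = 0L,
                         nasal_congestion = 0L, itchy_eyes = 0L, watery_eyes = 0L,
                         antihistamine = 0L, local_corticosteroid = 0L,
                         systemic_corticosteroid = 0L, vas = 0) {
  out <- tibble(
    patient_id = as.character(patient_id),
    day = as.Date(day),
    entry_day = as.Date(entry_day),
    sneezing = as.integer(sneezing),
    rhinorrhea = as.integer(rhinorrhea),
    nasal_pruritus = as.integer(nasal_pruritus),
    nasal_congestion = as.integer(nasal_congestion),
    itchy_eyes = as.integer(itchy_eyes),
    watery_eyes = as.integer(watery_eyes),
    antihistamine = as.integer(antihistamine),
    local_corticosteroid = as.integer(local_corticosteroid),
    systemic_corticosteroid = as.integer(systemic_corticosteroid),
    vas = as.numeric(vas)
  )
  check_diary(out)
  out
}

#' Build a prescription-window tibble
#'
#' One row per patient: the doctor-assigned monitoring interval (prescription
#' period) during which daily diary entry was requested. Both ends inclusive.
#'
#' @param patient_id Patient identifier(s).
#' @param start,end First and last prescribed day (`Date` or ISO-8601 string).
#' @return A tibble with columns `patient_id`, `start`, `end`, `duration`
#'   (calendar days, `end - start + 1`).
#' @examples
#' prescription_window("P001", "2016-04-01", "2016-05-24")
#' @export
prescription_window <- function(patient_id, start, end) {
  out <- tibble(
    patient_id = as.character(patient_id),
    start = as.Date(start),
    end = as.Date(end)
  )
  if (any(is.na(out$start)) || any(is.na(out$end))) {
    abort("prescription windows contain unparsable dates")
  }
  if (any(out$end < out$start)) {
    bad <- out$patient_id[out$end < out$start]
    abort(paste0("prescription end precedes start for: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(out$patient_id)) {
    abort("duplicated patient_id in prescription windows")
  }
  out$duration <- as.integer(out$end - out$start) + 1L
  out
}

# Strict validation of the diary contract; errors name the offending field.
check_diary <- function(records, require_entry_rule = FALSE) {
  missing <- setdiff(DIARY_COLS, names(records))
  if (length(missing) > 0) {
    abort(paste0("diary is missing required column(s): ", paste(missing, collapse = ", ")))
  }
  for (col in SYMPTOM_COLS) {
    v <- records[[col]]
    if (any(is.na(v)) || any(!v %in% 0:3)) {
      abort(paste0("invalid severity in field '", col, "': values must be in 0..3"))
    }
  }
  for (col in MEDICATION_COLS) {
    v <- records[[col]]
    if (any(is.na(v)) || any(!v %in% 0:1)) {
      abort(paste0("invalid indicator in field '", col, "': values must be 0 or 1"))
    }
  }
  if (any(is.na(records$vas)) || any(records$vas < 0 | records$vas > 10)) {
    abort("invalid value in field 'vas': values must lie in [0, 10]")
  }
  if (require_entry_rule) {
    gap <- as.integer(records$entry_day - records$day)
    if (any(!gap %in% 0:1)) {
      abort("invalid entry_day: entries must be made the same day or the following one")
    }
  }
  invisible(records)
}

#' Rhinoconjunctivitis Total Symptom Score (RTSS)
#'
#' Sum of the six 0-3 symptom severities (four nasal, two ocular); range 0-18.
#'
#' @param records A diary tibble (see [diary_record()]).
#' @return Integer vector, one score per record.
#' @examples
#' compute_rtss(diary_record("P001", "2016-05-10", sneezing = 3, rhinorrhea = 2))
#' @export
compute_rtss <- function(records) {
  check_diary(records)
  as.integer(rowSums(as.matrix(records[SYMPTOM_COLS])))
}

#' Combined symptom and medication score (CSMS)
#'
#' Daily symptom score dSS (mean of the six 0-3 severities) plus daily
#' medication score dMS, where the highest medication class taken that day
#' counts: 0 none, 1 antihistamine, 2 local corticosteroid, 3 systemic
#' corticosteroid. Range 0-6.
#'
#' @inheritParams compute_rtss
#' @return Numeric vector, one score per record.
#' @export
compute_csms <- function(records) {
  check_diary(records)
  dss <- rowMeans(as.matrix(records[SYMPTOM_COLS]))
  dms <- pmax(
    3L * records$systemic_corticosteroid,
    2L * records$local_corticosteroid,
    1L * records$antihistamine
  )
  dss + dms
}

#' Add score columns to a diary
#'
#' Convenience wrapper appending `rtss` and `csms` columns (VAS is already a
#' column of the diary).
#'
#' @inheritParams compute_rtss
#' @return The diary tibble with `rtss` and `csms` appended.
#' @export
score_diary <- function(records) {
  records$rtss <- compute_rtss(records)
  records$csms <- compute_csms(records)
  as_tibble(records)
}

#' Validate and clean a diary against prescription windows
#'
#' Applies the diary's structural rules and returns the cleaned records plus a
#' per-record issue report. Rules, in order:
#'
#' * entries made more than one day after the day they refer to (or before it)
#'   are rejected (`late_entry`) — only same-day or next-day entry is allowed;
#' * duplicate records for the same patient-day are resolved by keeping the
#'   earliest `entry_day` (ties: first occurrence); the rest are rejected
#'   (`duplicate_day`);
#' * records dated outside the patient's prescription window are *kept* (the
#'   reporting period reflects actual behaviour) but flagged
#'   (`outside_prescription`).
#'
#' @param records A diary tibble.
#' @param windows A prescription-window tibble covering every patient present
#'   in `records`.
#' @return A list with elements `records` (cleaned tibble) and `issues`
#'   (tibble with `patient_id`, `day`, `entry_day`, `reason`, `action`).
#' @export
validate_records <- function(records, windows) {
  empty_issues <- tibble(
    patient_id = character(), day = as.Date(character()),
    entry_day = as.Date(character()), reason = character(), action = character()
  )
  if (nrow(records) == 0) {
    return(list(records = as_tibble(records), issues = empty_issues))
  }
  check_diary(records)
  unknown <- setdiff(unique(records$patient_id), windows$patient_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "diary records without a prescription window: ",
      paste(unknown, collapse = ", ")
    ))
  }

  records <- as_tibble(records)
  gap <- as.integer(records$entry_day - records$day)
  late <- !gap %in% 0:1
  issues <- records[late, c("patient_id", "day", "entry_day")]
  issues$reason <- "late_entry"
  issues$action <- "rejected"
  kept <- records[!late, , drop = FALSE]

  # duplicate days: keep the earliest entry (favours non-postponed data)
  kept <- kept[order(kept$patient_id, kept$day, kept$entry_day), , drop = FALSE]
  dup <- duplicated(kept[c("patient_id", "day")])
  if (any(dup)) {
    di <- kept[dup, c("patient_id", "day", "entry_day")]
    di$reason <- "duplicate_day"
    di$action <- "rejected"
    issues <- bind_rows(issues, di)
    kept <- kept[!dup, , drop = FALSE]
  }

  w <- windows[match(kept$patient_id, windows$patient_id), ]
  outside <- kept$day < w$start | kept$day > w$end
  if (any(outside)) {
    oi <- kept[outside, c("patient_id", "day", "entry_day")]
    oi$reason <- "outside_prescription"
    oi$action <- "flagged"
    issues <- bind_rows(issues, oi)
  }

  issues <- if (nrow(issues) == 0) empty_issues else as_tibble(issues)
  list(records = kept, issues = arrange(issues, .data$patient_id, .data$day))
}
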