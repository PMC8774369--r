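# Cohort tables: many patient-visits in one data frame, read and written as
# CSV or JSON. Fixed schema, one column per sub-axis:
#   patient_id, years_from_onset,
#   m_fluct, m_dysk, m_axial, m_tremor,
#   n_neuropsych, n_autonomic, n_sleep_fatigue, n_pain_sensory,
#   cognition, dependency
# Unknown columns are preserved on round-trip but carry no meaning here.
# Derived columns (notation, M, N, stage, table3_conformant) are written on
# request and never read back as authoritative.

cohort_error <- function(msg) {
  stop(errorCondition(msg, class = "mncd_cohort_error"))
}

#' Coerce a data frame to a validated cohort table
#'
#' Checks the fixed schema (see [read_cohort()]), value ranges, and
#' uniqueness of `(patient_id, years_from_onset)` pairs. Range violations
#' are errors naming the row and column; the dementia-without-dependency
#' coherence issue is reported as an R warning and the row is kept.
#'
#' @param df a data frame with at least the schema columns.
#' @return The validated data frame with class `mncd_cohort`.
#' @export
as_mncd_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols)) {
    cohort_error(paste("cohort is missing required column(s):",
                       paste(missing_cols, collapse = ", ")))
  }
  df$patient_id <- as.character(df$patient_id)
  for (nm in c("years_from_onset", RECORD_COLUMNS)) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad_na <- is.na(v) & !is.na(df[[nm]])
    if (any(bad_na)) {
      cohort_error(sprintf("row %d, column %s: not a number (%s)",
                           which(bad_na)[1], nm,
                           df[[nm]][which(bad_na)[1]]))
    }
    df[[nm]] <- v
  }
  for (nm in RECORD_COLUMNS) {
    rng <- if (nm %in% c("cognition", "dependency")) 0:2 else 0:1
    bad <- which(is.na(df[[nm]]) | !df[[nm]] %in% rng)
    if (length(bad)) {
      cohort_error(sprintf("row %d, column %s: value %s outside {%s}",
                           bad[1], nm, df[[nm]][bad[1]],
                           paste(rng, collapse = ",")))
    }
    df[[nm]] <- as.integer(df[[nm]])
  }
  bad_t <- which(is.na(df$years_from_onset) | df$years_from_onset < 0)
  if (length(bad_t)) {
    cohort_error(sprintf(
      "row %d, column years_from_onset: must be a non-negative number",
      bad_t[1]))
  }
  key <- paste(df$patient_id, df$years_from_onset, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    cohort_error(sprintf(
      "duplicate visit: patient_id=%s at years_from_onset=%s",
      df$patient_id[dup[1]], df$years_from_onset[dup[1]]))
  }
  incoher <- which(df$cognition == 2L & df$dependency == 0L)
  if (length(incoher)) {
    warning(sprintf(
      paste("%d row(s) record dementia (cognition=2) with full ADL",
            "independence (dependency=0), which is clinically incoherent;",
            "rows kept (first: row %d, patient %s)"),
      length(incoher), incoher[1], df$patient_id[incoher[1]]),
      call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- unique(c("mncd_cohort", class(df)))
  df
}

guess_format <- function(path, format) {
  format <- match.arg(format, c("auto", "csv", "json"))
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else
    cohort_error(sprintf("cannot infer format from extension of %s", path))
}

#' Read a cohort of MNCD records
#'
#' Reads per-visit axis ratings from CSV (UTF-8, comma-delimited, header
#' mandatory) or JSON (an array of record objects with the same field
#' names). Required columns: `patient_id`, `years_from_onset`, the eight
#' sub-axis flags `m_fluct`, `m_dysk`, `m_axial`, `m_tremor`,
#' `n_neuropsych`, `n_autonomic`, `n_sleep_fatigue`, `n_pain_sensory`, and
#' `cognition`, `dependency`. Times are years from symptom onset as
#' decimals, not calendar dates.
#'
#' If the file carries derived columns (`notation`, `M`, `N`, `stage`,
#' `table3_conformant`), they are not trusted: each is recomputed from the
#' flags, mismatches raise warnings, and the stored copies are dropped.
#'
#' @param path file to read.
#' @param format `"csv"`, `"json"`, or `"auto"` (default: by extension).
#' @return An `mncd_cohort` data frame (see [as_mncd_cohort()]).
#' @seealso [write_cohort()], [stage_cohort()]
#' @export
read_cohort <- function(path, format = "auto") {
  format <- guess_format(path, format)
  if (!file.exists(path)) cohort_error(paste("no such file:", path))
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = c(patient_id = "character"),
                    fileEncoding = "UTF-8")
  } else {
    out <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(out) == 0L) out <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(COHORT_COLUMNS))),
      COHORT_COLUMNS)
    as.data.frame(out, stringsAsFactors = FALSE)
  }
  stored <- intersect(DERIVED_COLUMNS, names(df))
  cohort <- as_mncd_cohort(df[setdiff(names(df), stored)])
  if (length(stored) && nrow(cohort)) {
    fresh <- derive_columns(cohort)
    for (nm in stored) {
      disagree <- which(as.character(df[[nm]]) != as.character(fresh[[nm]]))
      if (length(disagree)) {
        warning(sprintf(
          "stored derived column '%s' disagrees with recomputed values in %d row(s) (first: row %d); recomputed values used",
          nm, length(disagree), disagree[1]), call. = FALSE)
      }
    }
  }
  cohort
}

#' Write a cohort of MNCD records
#'
#' Writes the cohort in the schema of [read_cohort()]. With
#' `with_derived = TRUE` the recomputed `notation`, `M`, `N`, `stage` and
#' `table3_conformant` columns are appended. Output is deterministic:
#' identical cohorts and options produce identical bytes.
#'
#' @param cohort an `mncd_cohort` (or coercible data frame).
#' @param path file to write.
#' @param format `"csv"`, `"json"`, or `"auto"` (default: by extension).
#' @param with_derived append derived columns (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = "auto", with_derived = FALSE) {
  format <- guess_format(path, format)
  cohort <- as_mncd_cohort(cohort)
  out <- if (with_derived) stage_cohort(cohort) else
    cohort[setdiff(names(cohort), DERIVED_COLUMNS)]
  out <- as.data.frame(out)
  status <- try({
    if (format == "csv") {
      utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
    } else {
      jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                           auto_unbox = FALSE, pretty = TRUE, na = "null")
    }
  }, silent = TRUE)
  if (inherits(status, "try-error")) {
    cohort_error(sprintf("failed to write %s: %s", path,
                         attr(status, "condition")$message))
  }
  invisible(path)
}

#' The five canonical worked examples
#'
#' A small built-in cohort of five illustrative patient profiles, one per
#' stage: an early patient with no relevant symptoms (stage 1), an isolated
#' disabling tremor (stage 2), motor complications with mild cognitive
#' impairment and instrumental-ADL dependency (stage 3), axial disease with
#' basic-ADL dependency but intact cognition (stage 4), and long-duration
#' disease with dementia and basic-ADL dependency (stage 5).
#'
#' @return An `mncd_cohort` with patient ids `ex1`..`ex5`.
#' @examples
#' stage_cohort(mncd_examples())[, c("patient_id", "notation", "stage")]
#' @export
mncd_examples <- function() {
  as_mncd_cohort(data.frame(
    patient_id = paste0("ex", 1:5),
    years_from_onset = c(5, 2, 6, 4, 20),
    m_fluct         = c(0, 0, 1, 0, 1),
    m_dysk          = c(0, 0, 1, 0, 0),
    m_axial         = c(0, 0, 1, 1, 1),
    m_tremor        = c(0, 1, 0, 0, 0),
    n_neuropsych    = c(0, 0, 1, 1, 1),
    n_autonomic     = c(0, 0, 0, 0, 1),
    n_sleep_fatigue = c(0, 0, 0, 1, 1),
    n_pain_sensory  = c(0, 0, 0, 1, 0),
    cognition       = c(0, 0, 1, 0, 2),
    dependency      = c(0, 0, 1, 2, 2),
    stringsAsFactors = FALSE))
}

#' Extract one patient's trajectory from a cohort
#'
#' @param cohort an `mncd_cohort`.
#' @param patient_id the patient to extract.
#' @return The patient's rows ordered by `years_from_onset`.
#' @export
patient_trajectory <- function(cohort, patient_id) {
  cohort <- as_mncd_cohort(cohort)
  rows <- cohort[cohort$patient_id == patient_id, , drop = FALSE]
  if (nrow(rows) == 0L) {
    cohort_error(paste("no visits for patient", patient_id))
  }
  rows <- rows[order(rows$years_from_onset), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
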