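# Core data model: one patient-visit's MNCD state.

MOTOR_FIELDS <- c("fluctuations", "dyskinesia", "axial", "tremor")
NONMOTOR_FIELDS <- c("neuropsychiatric", "autonomic", "sleep_fatigue",
                     "pain_sensory")

# Fixed CSV/JSON column names, one per sub-axis (see read_cohort()).
MOTOR_COLUMNS <- c("m_fluct", "m_dysk", "m_axial", "m_tremor")
NONMOTOR_COLUMNS <- c("n_neuropsych", "n_autonomic", "n_sleep_fatigue",
                      "n_pain_sensory")
RECORD_COLUMNS <- c(MOTOR_COLUMNS, NONMOTOR_COLUMNS, "cognition", "dependency")
COHORT_COLUMNS <- c("patient_id", "years_from_onset", RECORD_COLUMNS)
DERIVED_COLUMNS <- c("notation", "M", "N", "stage", "table3_conformant")

is_binary_flag <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x %in% c(0, 1)
}

check_flags <- function(flags, fields, what) {
  if (!is.numeric(flags) || length(flags) != 4L || anyNA(flags) ||
      !all(flags %in% c(0, 1))) {
    stop(sprintf("`%s` must be four 0/1 flags (%s)", what,
                 paste(fields, collapse = ", ")), call. = FALSE)
  }
  flags <- as.integer(flags)
  names(flags) <- fields
  flags
}

check_level <- function(level, what) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      !level %in% 0:2) {
    stop(sprintf("`%s` must be a single integer in 0, 1, 2", what),
         call. = FALSE)
  }
  as.integer(level)
}

#' Create an MNCD record for one patient visit
#'
#' An MNCD record captures a patient's state on the four axes of the MNCD
#' classification of Parkinson's disease at one evaluation moment:
#'
#' * **Motor** (`M`): four binary sub-axes — motor fluctuations, dyskinesia,
#'   axial symptoms, tremor. Each is 1 when the symptom is present and
#'   clinically relevant in the rater's judgment, 0 otherwise.
#' * **Non-motor** (`N`): four binary sub-axes — neuropsychiatric symptoms,
#'   autonomic dysfunction, sleep disturbances and fatigue, pain and sensory
#'   disorders.
#' * **Cognition** (`C`): 0 normal, 1 mild cognitive impairment, 2 dementia.
#' * **Dependency** (`D`): 0 independent for activities of daily living (ADL),
#'   1 dependent for instrumental ADL, 2 dependent for basic ADL.
#'
#' The axis subscripts M and N are always *derived* (the count of positive
#' sub-axes); they are never stored. Time from symptom onset is kept in
#' fractional years so that, e.g., six months can be recorded as 0.5.
#'
#' @param motor numeric vector of four 0/1 flags, in the order
#'   fluctuations, dyskinesia, axial, tremor.
#' @param nonmotor numeric vector of four 0/1 flags, in the order
#'   neuropsychiatric, autonomic, sleep_fatigue, pain_sensory.
#' @param cognition integer 0, 1 or 2.
#' @param dependency integer 0, 1 or 2.
#' @param years_from_onset non-negative number of years since symptom onset,
#'   or `NA` when unknown.
#' @param patient_id optional opaque patient identifier.
#' @param visit_label optional opaque visit label.
#' @return An object of class `mncd_record`.
#' @examples
#' r <- mncd_record(c(1, 0, 1, 0), c(1, 1, 1, 0), cognition = 2,
#'                  dependency = 2, years_from_onset = 20)
#' format_notation(r)
#' mncd_stage(r)
#' @seealso [mncd_stage()], [format_notation()], [parse_notation()]
#' @export
mncd_record <- function(motor, nonmotor, cognition, dependency,
                        years_from_onset = NA_real_,
                        patient_id = NA_character_,
                        visit_label = NA_character_) {
  motor <- check_flags(motor, MOTOR_FIELDS, "motor")
  nonmotor <- check_flags(nonmotor, NONMOTOR_FIELDS, "nonmotor")
  cognition <- check_level(cognition, "cognition")
  dependency <- check_level(dependency, "dependency")
  if (!is.na(years_from_onset)) {
    if (!is.numeric(years_from_onset) || length(years_from_onset) != 1L ||
        years_from_onset < 0) {
      stop("`years_from_onset` must be a single non-negative number",
           call. = FALSE)
    }
  }
  structure(
    list(motor = motor, nonmotor = nonmotor, cognition = cognition,
         dependency = dependency,
         years_from_onset = as.numeric(years_from_onset),
         patient_id = as.character(patient_id),
         visit_label = as.character(visit_label)),
    class = "mncd_record"
  )
}

#' Motor and non-motor axis scores
#'
#' The M (respectively N) subscript of the MNCD notation: the number of
#' positive sub-axes, 0 to 4.
#'
#' @param x an `mncd_record`, or a numeric vector of four 0/1 flags.
#' @return Integer in 0..4.
#' @examples
#' motor_score(c(1, 1, 1, 0))   # 3
#' nonmotor_score(c(1, 0, 1, 1))  # 3
#' @export
motor_score <- function(x) {
  if (inherits(x, "mncd_record")) x <- x$motor
  sum(check_flags(x, MOTOR_FIELDS, "motor"))
}

#' @rdname motor_score
#' @export
nonmotor_score <- function(x) {
  if (inherits(x, "mncd_record")) x <- x$nonmotor
  sum(check_flags(x, NONMOTOR_FIELDS, "nonmotor"))
}

issue_row <- function(severity, axis, message) {
  data.frame(severity = severity, axis = axis, message = message,
             stringsAsFactors = FALSE)
}

empty_issues <- function() {
  data.frame(severity = character(), axis = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate an MNCD record
#'
#' Checks the clinical coherence of a record and returns the issues found,
#' never raising an error. A well-formed `mncd_record` cannot carry
#' out-of-range components (the constructor rejects them), but records built
#' from raw tabular rows may; those surface here as `ERROR` issues.
#'
#' One coherence rule is checked at `WARNING` (non-fatal) level: dementia
#' (`cognition = 2`) together with full ADL independence (`dependency = 0`).
#' Dementia is defined by overt functional decline, so this combination is
#' clinically incoherent, but the record is kept and can still be staged —
#' rater-entered data is never discarded.
#'
#' @param record an `mncd_record`, or a list/one-row data frame with the
#'   cohort column names (`m_fluct`, ..., `cognition`, `dependency`).
#' @return A data frame with columns `severity` (`"ERROR"`/`"WARNING"`),
#'   `axis`, and `message`; zero rows when the record is coherent.
#' @examples
#' validate_record(mncd_record(rep(0, 4), rep(0, 4), 2, 0))
#' @export
validate_record <- function(record) {
  if (inherits(record, "mncd_record")) {
    comp <- c(as.list(record$motor), as.list(record$nonmotor),
              cognition = record$cognition, dependency = record$dependency)
    names(comp)[1:8] <- RECORD_COLUMNS[1:8]
    t_onset <- record$years_from_onset
  } else {
    record <- as.list(record)
    comp <- record[intersect(RECORD_COLUMNS, names(record))]
    t_onset <- record$years_from_onset
  }
  issues <- empty_issues()
  for (nm in RECORD_COLUMNS) {
    v <- comp[[nm]]
    rng <- if (nm %in% c("cognition", "dependency")) 0:2 else 0:1
    if (is.null(v) || length(v) != 1L || is.na(suppressWarnings(as.numeric(v))) ||
        !as.numeric(v) %in% rng) {
      issues <- rbind(issues, issue_row(
        "ERROR", nm,
        sprintf("%s must be in {%s}; got %s", nm,
                paste(rng, collapse = ","),
                if (is.null(v)) "nothing" else paste(v, collapse = ","))))
    }
  }
  if (!is.null(t_onset) && length(t_onset) == 1L && !is.na(t_onset) &&
      is.numeric(t_onset) && t_onset < 0) {
    issues <- rbind(issues, issue_row(
      "ERROR", "years_from_onset", "years_from_onset must be non-negative"))
  }
  if (nrow(issues) == 0L &&
      as.integer(comp$cognition) == 2L && as.integer(comp$dependency) == 0L) {
    issues <- rbind(issues, issue_row(
      "WARNING", "cognition/dependency",
      paste("dementia (cognition=2) recorded with full ADL independence",
            "(dependency=0): clinically incoherent, record kept")))
  }
  issues
}

#' @export
format.mncd_record <- function(x, ...) format_notation(x, include_time = NULL)

#' @export
print.mncd_record <- function(x, ...) {
  st <- mncd_stage(x)
  cat("<MNCD record> ", format_notation(x, include_time = NULL), "\n", sep = "")
  if (!is.na(x$patient_id)) cat("  patient:", x$patient_id, "\n")
  cat("  stage:", st$stage,
      if (!st$table3_conformant) "(outside the literal staging rule rows)",
      "\n")
  inv <- validate_record(x)
  if (nrow(inv)) cat("  issues:", paste(inv$message, collapse = "; "), "\n")
  invisible(x)
}

# One-row data frame in the cohort schema (no derived columns).
record_to_row <- function(record) {
  row <- as.list(c(record$motor, record$nonmotor))
  names(row) <- RECORD_COLUMNS[1:8]
  row <- c(list(patient_id = record$patient_id,
                years_from_onset = record$years_from_onset),
           row,
           list(cognition = record$cognition,
                dependency = record$dependency))
  as.data.frame(row, stringsAsFactors = FALSE)
}

row_to_record <- function(row) {
  mncd_record(
    motor = as.numeric(row[MOTOR_COLUMNS]),
    nonmotor = as.numeric(row[NONMOTOR_COLUMNS]),
    cognition = as.numeric(row[["cognition"]]),
    dependency = as.numeric(row[["dependency"]]),
    years_from_onset = if ("years_from_onset" %in% names(row))
      as.numeric(row[["years_from_onset"]]) else NA_real_,
    patient_id = if ("patient_id" %in% names(row))
      as.character(row[["patient_id"]]) else NA_character_,
    visit_label = if ("visit_label" %in% names(row))
      as.character(row[["visit_label"]]) else NA_character_
  )
}

#' Enumerate the full MNCD state space
#'
#' The classification has 2^4 motor flag combinations, 2^4 non-motor flag
#' combinations, 3 cognition levels and 3 dependency levels: 2304 distinct
#' states in all. Useful for exhaustive audits of the staging rule and the
#' notation codec.
#'
#' @return A 2304-row data frame with one column per sub-axis flag plus
#'   `cognition` and `dependency`.
#' @examples
#' nrow(enumerate_states())  # 2304
#' @export
enumerate_states <- function() {
  grid <- expand.grid(
    m_fluct = 0:1, m_dysk = 0:1, m_axial = 0:1, m_tremor = 0:1,
    n_neuropsych = 0:1, n_autonomic = 0:1, n_sleep_fatigue = 0:1,
    n_pain_sensory = 0:1,
    cognition = 0:2, dependency = 0:2,
    KEEP.OUT.ATTRS = FALSE)
  grid[RECORD_COLUMNS]
}
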