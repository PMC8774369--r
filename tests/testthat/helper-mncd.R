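# Independently coded staging oracle: the literal published rule rows as
# predicates, checked bottom-up, plus the documented fallback for dementia
# without basic-ADL dependency. Deliberately structured differently from the
# package's vectorized top-down implementation.
oracle_stage <- function(M, N, C, D) {
  if (M == 0 && N == 0 && C == 0 && D == 0) return(1L)
  if ((M >= 1 || N >= 1) && C == 0 && D == 0) return(2L)
  if (C == 2 && D == 2) return(5L)
  if (D == 2 && C <= 1) return(4L)
  if (C == 1 || D == 1) return(3L)
  3L  # fallback: C=2 with D<=1, staged as cognitive-impairment stage
}

state_to_record <- function(row, years = NA_real_) {
  mncd_record(
    motor = as.numeric(row[c("m_fluct", "m_dysk", "m_axial", "m_tremor")]),
    nonmotor = as.numeric(row[c("n_neuropsych", "n_autonomic",
                                "n_sleep_fatigue", "n_pain_sensory")]),
    cognition = row[["cognition"]], dependency = row[["dependency"]],
    years_from_onset = years)
}

# Render a record in the typographic print dialect (underscored subscripts,
# en dash before the time suffix) for parser-liberality tests.
typographic_notation <- function(record, include_time = TRUE) {
  ascii <- format_notation(record, include_time = include_time)
  out <- sub("^M(\\d)N(\\d)C(\\d)D(\\d)", "M_\\1_N_\\2_C_\\3_D_\\4_", ascii)
  sub("-(\\d[0-9.]*)$", "–\\1", out)
}

# The five worked example profiles as (notation, stage) pairs.
worked_examples <- function() {
  data.frame(
    notation = c("M0N0C0D0 (0000/0000/0/0)-5",
                 "M1N0C0D0 (0001/0000/0/0)-2",
                 "M3N1C1D1 (1110/1000/1/1)-6",
                 "M1N3C0D2 (0010/1011/0/2)-4",
                 "M2N3C2D2 (1010/1110/2/2)-20"),
    stage = 1:5,
    stringsAsFactors = FALSE)
}

run_cli <- function(args, input = NULL) {
  cli <- system.file("cli", "mncd.R", package = "mncd")
  stopifnot(nzchar(cli))
  res <- suppressWarnings(system2(
    "Rscript", c(shQuote(cli), shQuote(args)), stdout = TRUE, stderr = TRUE,
    input = input,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  status <- attr(res, "status")
  list(status = if (is.null(status)) 0L else status, output = as.character(res))
}
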