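# Longitudinal summaries: stage over time, time-in-stage, transitions.
# The stage is defined only at evaluation moments, so between visits it is
# held constant (right-continuous step function): the interval from visit i
# to visit i+1 is attributed to the stage observed at visit i, and the last
# visit contributes no further time.

#' Summarize one patient's stage trajectory
#'
#' Computes the stage at every visit, the time spent in each stage (step
#' function between visits), the 5x5 matrix of visit-to-visit stage
#' transitions and the number of stage regressions (transitions to a lower
#' stage).
#'
#' @param traj a cohort table holding one patient's visits (e.g. from
#'   [patient_trajectory()]); a multi-patient cohort plus `patient_id`
#'   also works.
#' @param patient_id optional: select this patient from `traj` first.
#' @return An object of class `mncd_trajectory_summary` with elements
#'   `patient_id`, `times`, `stages`, `time_in_stage` (named numeric, years
#'   per stage, summing to the follow-up duration), `transition_counts`
#'   (5x5 integer matrix, rows = from, cols = to), `regressions` and
#'   `n_visits`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_patients = 2, seed = 7))
#' summarize_trajectory(coh, patient_id = "p0001")
#' @export
summarize_trajectory <- function(traj, patient_id = NULL) {
  traj <- as_mncd_cohort(traj)
  if (!is.null(patient_id)) {
    traj <- patient_trajectory(traj, patient_id)
  } else {
    ids <- unique(traj$patient_id)
    if (length(ids) != 1L) {
      stop("trajectory spans more than one patient; give `patient_id`",
           call. = FALSE)
    }
    traj <- patient_trajectory(traj, ids)
  }
  if (nrow(traj) == 0L) stop("empty trajectory", call. = FALSE)
  times <- traj$years_from_onset
  stages <- stage_level(rowSums(traj[MOTOR_COLUMNS]),
                        rowSums(traj[NONMOTOR_COLUMNS]),
                        traj$cognition, traj$dependency)
  time_in_stage <- stats::setNames(numeric(5), 1:5)
  if (length(times) > 1L) {
    held <- diff(times)
    for (i in seq_along(held)) {
      time_in_stage[stages[i]] <- time_in_stage[stages[i]] + held[i]
    }
  }
  trans <- matrix(0L, 5, 5, dimnames = list(from = 1:5, to = 1:5))
  if (length(stages) > 1L) {
    for (i in seq_len(length(stages) - 1L)) {
      trans[stages[i], stages[i + 1L]] <- trans[stages[i], stages[i + 1L]] + 1L
    }
  }
  structure(list(
    patient_id = traj$patient_id[1],
    times = times, stages = stages,
    time_in_stage = time_in_stage,
    transition_counts = trans,
    regressions = sum(diff(stages) < 0),
    n_visits = length(stages)
  ), class = "mncd_trajectory_summary")
}

#' @export
print.mncd_trajectory_summary <- function(x, ...) {
  cat(sprintf("<MNCD trajectory> patient %s, %d visit(s)\n",
              x$patient_id, x$n_visits))
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  tis <- x$time_in_stage[x$time_in_stage > 0]
  if (length(tis)) {
    cat("  time in stage:",
        paste(sprintf("%s: %g y", names(tis), tis), collapse = ", "), "\n")
  }
  cat("  regressions:", x$regressions, "\n")
  invisible(x)
}

#' Summarize every trajectory in a cohort
#'
#' @param cohort an `mncd_cohort`.
#' @return A list with `per_patient` (named list of
#'   [summarize_trajectory()] results), the pooled `transition_counts`
#'   matrix and the total number of `regressions`.
#' @export
summarize_cohort <- function(cohort) {
  cohort <- as_mncd_cohort(cohort)
  ids <- unique(cohort$patient_id)
  per <- lapply(ids, function(id) summarize_trajectory(cohort, id))
  names(per) <- ids
  trans <- Reduce(`+`, lapply(per, `[[`, "transition_counts"),
                  matrix(0L, 5, 5, dimnames = list(from = 1:5, to = 1:5)))
  list(per_patient = per,
       transition_counts = trans,
       regressions = as.integer(sum(vapply(per, `[[`, numeric(1),
                                           "regressions"))))
}
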