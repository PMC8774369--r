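# Discrete-time stochastic simulator of longitudinal MNCD cohorts.
#
# The classification is administered at clinical visits, so the dynamics are
# per-visit Markov steps rather than continuous-time hazards. Every patient
# starts in the implicit all-zero state at symptom onset (t = 0) and is
# assessed at t = dt, 2*dt, ... up to the horizon. Per step of length dt:
#   * each 0-flag turns on with probability 1 - (1 - h)^dt, h its annual
#     onset hazard;
#   * each 1-flag reverts to 0 with the analogous remission probability
#     (default hazards 0: symptoms accrue monotonically);
#   * dependency D advances by at most one level with its annual hazard;
#   * cognition C advances by at most one level with its annual hazard;
#     with dementia-dependency coupling on, the step C: 1 -> 2 is only
#     allowed while D >= 1 (dementia implies functional decline).
# D is updated before C within a step so the coupling gate sees the current
# visit's dependency level.

FLAG_HAZARD_NAMES <- c(MOTOR_COLUMNS, NONMOTOR_COLUMNS)

recycle_hazards <- function(x, what) {
  if (length(x) == 1L) x <- rep(x, 8L)
  if (length(x) != 8L || !is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop(sprintf("`%s` must be 1 or 8 probabilities in [0, 1]", what),
         call. = FALSE)
  }
  if (is.null(names(x))) names(x) <- FLAG_HAZARD_NAMES
  x[FLAG_HAZARD_NAMES]
}

#' Configure a cohort simulation
#'
#' Builds a validated simulation configuration. Hazards are annual
#' probabilities; the per-step probability over a visit interval of `dt`
#' years is `1 - (1 - hazard)^dt`.
#'
#' @param n_patients number of patients.
#' @param horizon_years follow-up duration in years.
#' @param visit_interval_years years between consecutive visits.
#' @param onset_hazard_per_flag annual onset probability for each of the 8
#'   sub-axis flags (scalar recycled, or a vector of 8 in cohort column
#'   order `m_fluct` .. `n_pain_sensory`).
#' @param cognition_progression_hazard annual probability that cognition
#'   advances one level (0 to 1, or 1 to 2).
#' @param dependency_progression_hazard annual probability that dependency
#'   advances one level.
#' @param couple_dementia_dependency when `TRUE` (default), cognition can
#'   only reach 2 (dementia) while dependency is at least 1, reflecting that
#'   dementia entails functional decline.
#' @param remission_hazards annual probability that a set flag reverts to 0
#'   (scalar or vector of 8; default 0, i.e. no remission).
#' @param seed integer seed; identical configurations (including the seed)
#'   reproduce identical cohorts bit for bit.
#' @return An object of class `mncd_sim_config`.
#' @seealso [simulate_cohort()], [preset_scenarios()]
#' @export
sim_config <- function(n_patients = 100,
                       horizon_years = 10,
                       visit_interval_years = 1,
                       onset_hazard_per_flag = 0.1,
                       cognition_progression_hazard = 0.05,
                       dependency_progression_hazard = 0.05,
                       couple_dementia_dependency = TRUE,
                       remission_hazards = 0,
                       seed = 1L) {
  stopifnot(length(n_patients) == 1L, n_patients >= 1,
            n_patients == round(n_patients),
            length(horizon_years) == 1L, length(visit_interval_years) == 1L,
            is.logical(couple_dementia_dependency),
            length(seed) == 1L, is.finite(seed))
  if (!(visit_interval_years > 0) || horizon_years < visit_interval_years) {
    stop("need horizon_years >= visit_interval_years > 0", call. = FALSE)
  }
  check_p <- function(p, what) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop(sprintf("`%s` must be a probability in [0, 1]", what),
           call. = FALSE)
    }
    p
  }
  structure(list(
    n_patients = as.integer(n_patients),
    horizon_years = as.numeric(horizon_years),
    visit_interval_years = as.numeric(visit_interval_years),
    onset_hazard_per_flag = recycle_hazards(onset_hazard_per_flag,
                                            "onset_hazard_per_flag"),
    cognition_progression_hazard =
      check_p(cognition_progression_hazard, "cognition_progression_hazard"),
    dependency_progression_hazard =
      check_p(dependency_progression_hazard, "dependency_progression_hazard"),
    couple_dementia_dependency = isTRUE(couple_dementia_dependency),
    remission_hazards = recycle_hazards(remission_hazards,
                                        "remission_hazards"),
    seed = as.integer(seed)
  ), class = "mncd_sim_config")
}

#' @export
print.mncd_sim_config <- function(x, ...) {
  cat("<MNCD simulation config>\n")
  cat(sprintf("  %d patients, %g y horizon, visits every %g y, seed %d\n",
              x$n_patients, x$horizon_years, x$visit_interval_years, x$seed))
  cat(sprintf("  flag onset hazards: %s\n",
              paste(signif(x$onset_hazard_per_flag, 3), collapse = " ")))
  cat(sprintf("  C/D progression hazards: %g / %g (coupling %s)\n",
              x$cognition_progression_hazard,
              x$dependency_progression_hazard,
              if (x$couple_dementia_dependency) "on" else "off"))
  if (any(x$remission_hazards > 0)) {
    cat(sprintf("  remission hazards: %s\n",
                paste(signif(x$remission_hazards, 3), collapse = " ")))
  }
  invisible(x)
}

#' Read a simulation configuration from a JSON file
#'
#' Field names are exactly the arguments of [sim_config()]; missing fields
#' take their defaults.
#'
#' @param path JSON file.
#' @return An `mncd_sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(paste("unknown simulation config field(s):",
               paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(sim_config, raw)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Simulate a longitudinal MNCD cohort
#'
#' Runs the per-visit Markov dynamics described in [sim_config()] for every
#' patient and returns the assessments as a cohort table. All patients share
#' one random stream seeded once from the configuration, so identical
#' configurations give identical cohorts.
#'
#' @param config an [sim_config()] object.
#' @return An `mncd_cohort` with `n_patients * floor(horizon / interval)`
#'   rows; patient ids `p0001`, `p0002`, ... and visits at
#'   `years_from_onset = interval, 2 * interval, ...`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 3, seed = 42))
#' head(stage_cohort(cohort))
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "mncd_sim_config"))
  n <- config$n_patients
  dt <- config$visit_interval_years
  n_steps <- floor(config$horizon_years / dt + 1e-9)
  p_on <- 1 - (1 - config$onset_hazard_per_flag)^dt
  p_off <- 1 - (1 - config$remission_hazards)^dt
  p_c <- 1 - (1 - config$cognition_progression_hazard)^dt
  p_d <- 1 - (1 - config$dependency_progression_hazard)^dt

  flags <- matrix(0L, nrow = n, ncol = 8,
                  dimnames = list(NULL, FLAG_HAZARD_NAMES))
  C <- integer(n); D <- integer(n)
  pid <- sprintf("p%04d", seq_len(n))

  chunks <- vector("list", n_steps)
  with_seed(config$seed, {
    for (s in seq_len(n_steps)) {
      for (j in seq_len(8L)) {
        u <- stats::runif(n)
        turn_on <- flags[, j] == 0L & u < p_on[j]
        turn_off <- flags[, j] == 1L & u < p_off[j]
        flags[turn_on, j] <- 1L
        flags[turn_off, j] <- 0L
      }
      D <- D + as.integer(D < 2L & stats::runif(n) < p_d)
      c_ok <- C < 2L &
        !(config$couple_dementia_dependency & C == 1L & D < 1L)
      C <- C + as.integer(c_ok & stats::runif(n) < p_c)
      chunks[[s]] <- data.frame(
        patient_id = pid, years_from_onset = s * dt,
        flags, cognition = C, dependency = D,
        stringsAsFactors = FALSE)
    }
  })
  cohort <- do.call(rbind, chunks)
  cohort <- cohort[order(cohort$patient_id, cohort$years_from_onset), ]
  as_mncd_cohort(cohort)
}

#' Preset progression scenarios
#'
#' Three named configurations emulating archetypal disease courses seen in
#' longitudinal monitoring:
#'
#' * `"long_term_dementia"` — slow accrual of motor and non-motor symptoms
#'   over a long follow-up, with dementia arriving late.
#' * `"late_onset_rapid"` — an older-onset, rapidly progressing course:
#'   high cognition/dependency hazards and a short horizon to basic-ADL
#'   dependency with dementia.
#' * `"tremor_benign"` — a young tremor-dominant benign form: the tremor
#'   flag switches on early, can remit after intervention, and all other
#'   hazards stay near zero, so most patients hover at stage 2.
#'
#' Parameter values are illustrative, chosen to reproduce the qualitative
#' shape of each course, not estimated from data.
#'
#' @param n_patients cohort size used for every preset (default 500).
#' @param seed base seed; the presets use `seed`, `seed + 1`, `seed + 2`.
#' @return Named list of [sim_config()] objects.
#' @examples
#' names(preset_scenarios())
#' @export
preset_scenarios <- function(n_patients = 500, seed = 20220101L) {
  list(
    long_term_dementia = sim_config(
      n_patients = n_patients, horizon_years = 25, visit_interval_years = 1,
      onset_hazard_per_flag = 0.08,
      cognition_progression_hazard = 0.06,
      dependency_progression_hazard = 0.06,
      couple_dementia_dependency = TRUE,
      remission_hazards = 0, seed = seed),
    late_onset_rapid = sim_config(
      n_patients = n_patients, horizon_years = 10,
      visit_interval_years = 0.5,
      onset_hazard_per_flag = 0.25,
      cognition_progression_hazard = 0.35,
      dependency_progression_hazard = 0.35,
      couple_dementia_dependency = TRUE,
      remission_hazards = 0, seed = seed + 1L),
    tremor_benign = sim_config(
      n_patients = n_patients, horizon_years = 20, visit_interval_years = 1,
      onset_hazard_per_flag = c(0.02, 0.02, 0.02, 0.80,
                                0.02, 0.02, 0.02, 0.02),
      cognition_progression_hazard = 0.005,
      dependency_progression_hazard = 0.005,
      couple_dementia_dependency = TRUE,
      remission_hazards = c(0, 0, 0, 0.05, 0, 0, 0, 0),
      seed = seed + 2L)
  )
}
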