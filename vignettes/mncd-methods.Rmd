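---
title: "The MNCD classification: model, staging policy, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MNCD classification: model, staging policy, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mncd)
```

## The classification

Parkinson's disease is clinically heterogeneous: two patients with the same
disease duration can differ radically in motor complications, non-motor
burden, cognition and autonomy. The MNCD system condenses a patient's state
at one clinical visit into four axes:

* **M — Motor**, four binary sub-axes: motor fluctuations, dyskinesia,
  axial symptoms (freezing of gait, postural instability, dysphagia,
  dysarthrophonia, trunk posture changes), and tremor. Each sub-axis is 1
  when the symptom is present *and clinically relevant in the rater's
  judgment*, 0 otherwise. The subscript M is the count of positive
  sub-axes (0–4).
* **N — Non-motor**, four binary sub-axes: neuropsychiatric symptoms,
  autonomic dysfunction, sleep disturbances and fatigue, pain and sensory
  disorders. Subscript N analogous to M.
* **C — Cognition**, one ordinal level: 0 normal, 1 mild cognitive
  impairment (deficits confirmed but daily functioning retained), 2
  dementia (cognitive impairment *with* overt functional decline).
* **D — Dependency** for activities of daily living (ADL): 0 independent,
  1 dependent for instrumental ADL (shopping, finances, housework), 2
  dependent for basic ADL (bathing, dressing, eating).

The full state is written `M2N3C2D2 (1010/1110/2/2)-20`: subscripts, then
the flag blocks in axis order, then years from symptom onset after a dash.
The state space is finite: $2^4 \times 2^4 \times 3 \times 3 = 2304$
states, which is small enough that every staging and codec property in this
package is verified by exhaustive enumeration rather than sampling.

The package deliberately stops *upstream* of clinical judgment: it records
the rater's 0/1 call, it does not compute symptom relevance from scale
scores (no UPDRS/NMSS mappings), and it does not translate MNCD stages into
other constructs such as Hoehn–Yahr stages or "advanced PD" definitions.

### Score arithmetic and validation

`motor_score()` and `nonmotor_score()` are pure flag counts. The M and N
subscripts are therefore *derived data*: they are recomputed on every
serialization and never stored, so a record cannot drift out of internal
consistency. `validate_record()` returns issues instead of raising errors:
range violations in raw tabular input are `ERROR` issues, while the one
cross-axis coherence rule — dementia (`C = 2`) recorded together with full
ADL independence (`D = 0`) — is a `WARNING`. Dementia is defined by
functional decline, so that combination is clinically incoherent; but the
package never discards rater-entered data, so the record is kept, flagged,
and still staged.

## The notation codec

`format_notation()` emits one canonical ASCII dialect: plain subscripts,
ASCII hyphen before the time suffix, integers without a decimal point,
fractional years with at most two decimals and no trailing zeros. The
printed form of the classification uses typographic subscripts and an en
dash, which cannot round-trip through plain-text systems; the parser is
therefore liberal (it accepts `M_3_N_1_C_1_D_1_ (1110/1000/1/1)–6`, flexible
whitespace, and a trailing period) while the formatter is conservative.
`parse_notation()` enforces the subscript/flag-block redundancy and names
the offending axis on mismatch, which catches the most common transcription
error in a redundant notation.

Two open points in the notation were resolved as follows. The time suffix
is optional: nothing in the system's definition makes it mandatory, and a
cross-sectional state is meaningful without it. Time is a non-negative real
number of years: one of the canonical worked examples describes a patient
six months from onset, which an integer field cannot express, so `-0.5` is
legal output.

## The staging rule and its total-function policy

Five stages are defined by rule rows over the axis states:

| Stage | Rule |
|-------|------------------------------------------|
| 1 | M = 0, N = 0, C = 0, D = 0 |
| 2 | M ≥ 1 or N ≥ 1; C = 0; D = 0 |
| 3 | C = 1 and/or D = 1 (M, N free) |
| 4 | D = 2, C ≤ 1 (M, N free) |
| 5 | C = 2 and D = 2 (M, N free) |

Read literally, these rows overlap (a patient with C = 1 and D = 2 matches
the stage-3 narrative "and/or" as well as stage 4) and leave a gap: C = 2
with D ≤ 1 — dementia without basic-ADL dependency — matches no row, since
the stage-3 narrative says "cognitive impairment (no dementia)".
`mncd_stage()` resolves both with one policy: **rules are evaluated
top-down by severity (5 → 4 → 3 → 2 → 1) and the first match wins**, which
makes the function total and resolves overlaps in favor of the more severe
stage. The gap states are assigned stage 3 and flagged
`table3_conformant = FALSE` with an explanatory note. This is a package
policy, not part of the published rule set: the conformance flag preserves
auditability of exactly those states, and a rater can decide whether the
record is a data-entry error or a genuine atypical patient. Rejecting the
states outright was ruled out for the same reason the coherence check above
is a warning — the tool must stage whatever the rater entered.

Exhaustive enumeration confirms the policy's consequences: every one of the
2304 states receives exactly one stage; only the all-zero state is stage 1;
stage 2 covers the $2^8 - 1 = 255$ flag combinations with C = D = 0; the
stage is monotone non-decreasing in C and in D with everything else fixed;
and above stage 2 the motor/non-motor flags never influence the stage.

```{r audit}
enumerate_stage_distribution()
```

## Cohort files

Cohorts are flat tables, one row per visit, with one column per sub-axis
(`m_fluct`, `m_dysk`, `m_axial`, `m_tremor`, `n_neuropsych`, `n_autonomic`,
`n_sleep_fatigue`, `n_pain_sensory`, `cognition`, `dependency`) plus
`patient_id` and `years_from_onset`. CSV (UTF-8, comma, mandatory header)
and JSON (array of row objects) are supported; unknown columns ride along
untouched so site-specific metadata survives a round-trip. Times are
decimal years from onset, not calendar dates — date arithmetic is
site-specific and out of scope. Derived columns (`notation`, `M`, `N`,
`stage`, `table3_conformant`) can be written for spreadsheet consumers but
are never trusted on input: they are recomputed, compared, and the stored
copies dropped with a warning on mismatch, keeping a single source of truth.

## The cohort simulator

No real cohort rated with this classification exists yet, so all
longitudinal demonstrations and tests run on simulated patients.
`simulate_cohort()` implements discrete-time per-visit Markov dynamics: the
classification is defined only at clinical visits, so visit-step dynamics
match the measurement process, and a continuous-time model would add
machinery without adding observable behavior. Every patient starts in the
implicit all-zero state at symptom onset ($t = 0$) and is assessed at
$t = \Delta t, 2\Delta t, \dots$ up to the horizon; the onset state itself
is not emitted as a visit, since it is all-zero by construction for every
patient. Per step:

* each unset flag turns on with probability $1 - (1 - h)^{\Delta t}$,
  where $h$ is its annual onset hazard (a probability, so hazards compose
  correctly across visit intervals of any length);
* each set flag reverts with the analogous remission probability
  (default 0, giving monotone symptom accrual);
* dependency advances at most one level per step with its hazard, then
  cognition likewise — D before C, so that the dementia–dependency
  coupling gate (`couple_dementia_dependency`, on by default) can check
  the current visit's D: with the gate on, the step C: 1 → 2 is blocked
  while D = 0, encoding that dementia entails functional decline. One
  level per step is the simplest ordered-progression model; the visit
  interval controls effective speed.

One random stream is seeded once per cohort and patient order is fixed, so
identical configurations reproduce identical cohorts bit for bit; the
caller's random state is saved and restored. Under zero remission, every
flag, C and D sequence is non-decreasing, and by the staging monotonicity
above the stage trajectory is non-decreasing — an invariant the tests check
jointly across the simulator and the staging rule.

`preset_scenarios()` ships three archetypal courses used in longitudinal
monitoring illustrations: slow accrual with late dementia
(`long_term_dementia`: 25-year horizon, flag hazards 0.08/y, C/D hazards
0.06/y), an older-onset rapid course (`late_onset_rapid`: 10-year horizon,
half-year visits, flag hazards 0.25/y, C/D hazards 0.35/y), and a young
tremor-dominant benign form (`tremor_benign`: tremor onset hazard 0.80/y
with 0.05/y remission modeling post-intervention improvement, all other
hazards at or below 0.02/y). The parameter values are illustrative
choices tuned to reproduce each course's qualitative shape — the published
courses are narrative, not quantitative — and are fixed; with the default
cohort size of 500 the benign preset's median final stage is 2 and the
rapid course reaches stage 5 much earlier on average than the slow one.

What the simulator does *not* emulate: mortality and informative dropout,
treatment effects beyond flag remission, rater noise, correlation between
sub-axes (all hazards are independent given the current state), and
calendar-time effects. Passing simulator-based tests therefore demonstrates
the pipeline's correctness on data with known dynamics, not clinical
validity on real patients.

## Longitudinal summaries

`summarize_trajectory()` holds the stage constant from one visit to the
next (a right-continuous step function — the classification is defined only
at evaluation moments), so time-in-stage sums exactly to the follow-up
duration, the last visit contributing no time. Visit-to-visit transitions
are counted in a 5×5 matrix and stage-decreasing transitions are reported
as regressions; with zero remission they are provably absent, which the
tests exploit.

## Inter-rater agreement

Because sub-axis scoring is "clinically relevant at the discretion of the
neurologist", rater variability is a first-order question for the
classification, and the planned applicability work is a pairwise inter- and
intra-observer design. `agreement()` therefore computes, per rater pair and
averaged over pairs: observed agreement, Cohen's kappa, and weighted kappa
with linear ($1 - |i-j|/(k-1)$) or quadratic ($1 - (i-j)^2/(k-1)^2$)
weights for ordinal scales such as the 5 stages. Design choices:

* **Pairwise averaging, not Fleiss' kappa**, matching the pairwise study
  design; Fleiss is a possible extension.
* **Kappa is the metric** because it is the field standard for categorical
  rater agreement; the choice is an assumption, since no metric is
  prescribed by the classification itself.
* The **category set is an argument** (`categories = 1:5` for stages):
  marginals and weight distances must be defined on the full scale even
  when a sample does not realize every category.
* **Degenerate input** (all raters constant and identical) has chance
  agreement 1; kappa is reported as `NA` with a note rather than a
  spurious number, while observed agreement is still returned.
* The large-sample standard error
  $\mathrm{SE} = \sqrt{p_o(1-p_o)/n}\,/\,(1-p_e)$ is reported for
  orientation but never used to gate anything; exact small-sample
  inference is out of scope.

`rater_component_agreement()` gives the per-sub-axis view — which
components two raters actually disagree on — by aligning two cohorts on
`(patient_id, years_from_onset)` and comparing column-wise, including the
derived stage.

## Numerical and testing choices

Everything discrete is checked exhaustively: the 2304-state space for
staging (against an independently coded literal-rule oracle), the codec
round-trip in both dialects with and without the time suffix, and all 16
flag combinations per axis for the score arithmetic. Stochastic checks use
fixed seeds and 3-standard-error bands: one-step flag onset fractions at
10,000 patients, independent-rater kappa at 10,000 items, zero-remission
regression-freeness at 500 patients, and preset-course comparisons at 500
patients. These sizes keep the whole suite around a minute on one CPU while
making a 3-SE false alarm a ≲1%-per-check event.

The accompanying `scripts/acceptance.R` recomputes all of the above from a
fresh session (`--seed` controls every random draw) and writes the
quantities as JSON; see the README for how to run it.
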