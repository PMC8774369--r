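Package: mncd
Title: MNCD Multi-Axis Classification and Staging of Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the MNCD classification of Parkinson's disease, a
    four-axis system (Motor, Non-motor, Cognition, Dependency) with a compact
    notation such as "M2N3C2D2 (1010/1110/2/2)-20" and five derived disease
    stages. Provides a validated record type for per-visit axis ratings, a
    parser and formatter for the notation (tolerant of the typographic
    dialect, canonical ASCII output), a total staging function with
    conformance flagging, cohort input/output in CSV and JSON, a
    discrete-time stochastic simulator of longitudinal cohorts, trajectory
    summaries (time in stage, stage transitions), inter-rater agreement
    statistics (observed agreement, Cohen's kappa, weighted kappa), and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
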