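Package: dyadsync
Title: Cross-Recurrence Analysis of Child-Caregiver Prosodic Synchrony
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying moment-to-moment vocal coordination in
    child-caregiver dyads from diarized audio feature streams.  Builds paired
    per-speaker prosodic time series from second-by-second diarization and
    frame-level acoustic descriptors, quantifies coupling with cross-recurrence
    quantification analysis (CRQA), and carries the resulting synchrony metrics
    through a multi-stage inferential procedure: random-intercept linear mixed
    models compared by likelihood-ratio test, leave-one-subject-out parametric
    bootstrap sensitivity analysis, temporal-alignment permutation nulls for
    specificity to moment-to-moment coordination, and a sequential four-gate
    model selection with Monte Carlo family-wise error control.  Includes a
    synthetic dyad generator with known coupling, parenting-stress and
    caregiver-role effects for end-to-end validation, plus diarization
    reliability metrics, Bayesian correlation screening and test-retest ICC.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    lme4,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
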