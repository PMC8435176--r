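Package: sitless
Title: Crossover-Trial Analysis of Sitting, Sitting Less and Exercise Regimens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing three-regimen (sit / sit-less / exercise)
    crossover studies of metabolic health. Implements Steele single-pool
    non-steady-state tracer kinetics for two-step hyperinsulinaemic-euglycaemic
    clamp data (glucose rate of appearance and disappearance, endogenous glucose
    production, insulin-mediated EGP suppression, non-oxidative glucose
    disposal), indirect-calorimetry substrate oxidation and energy expenditure,
    activPAL-style posture-event summaries with MET-hour energy-expenditure
    estimation, muscle-metabolome signature analysis (internal-standard and
    dry-weight normalisation, participant-blocked empirical-Bayes moderated
    t-statistics, PLS-DA with VIP ranking, regimen-signature concordance), and
    crossover repeated-measures statistics. A seeded synthetic-cohort generator
    reproduces the statistical structure these stages assume, so the full
    pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
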