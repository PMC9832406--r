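Package: clinicsched
Title: Exact Multi-Criteria Scheduling of Capacity-Constrained Outpatient
    Waiting Lists
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-support tooling for booking outpatient waiting lists
    (developed around ophthalmology referral backlogs) into clinic appointment
    slots over a planning horizon.  Patients carry a referral-to-treatment time
    (RTT, weeks), a clinical risk category (R1/R2/R3) and a per-clinic distance
    score; clinics publish per-day slot capacities.  The package solves the
    resulting capacity-constrained assignment problem exactly -- maximizing any
    non-negative weighted combination of total RTT, total risk score and total
    distance score -- via an integer min-cost-flow formulation, with an LP
    relaxation and a branch-and-bound route for cross-validation, three
    independent verification oracles, tabular metric reports, a seeded
    synthetic cohort/calendar generator, a rolling-horizon re-optimization
    simulator, and a command-line interface over delimited text files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    boot,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
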