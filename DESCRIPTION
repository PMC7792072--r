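Package: platformtrial
Title: Design and Simulation of Staged Multi-Arm Platform Trials with
    Shared Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and simulating multi-arm, multi-stage
    platform trials in which experimental arms are added and dropped over
    time against shared control arms. Provides required-event and
    required-participant calculations for time-to-event endpoints
    (Schoenfeld and Freedman methods) and power for two-sample binary
    endpoints; classic O'Brien-Fleming group-sequential boundaries
    computed by recursive numerical integration; minimisation
    randomisation with a random element and per-stage resets; a cohort
    simulator with exponential progression-free survival, independent
    dropout censoring and Bernoulli minimal-residual-disease response; a
    staged trial engine that maintains concurrent-comparator sets and
    shared-control bookkeeping; bespoke proportional-hazards, log-rank,
    logistic and two-proportion analyses; and Monte-Carlo operating
    characteristics including family-wise error with shared controls and
    intersection-union success rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
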