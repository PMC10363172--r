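Package: depotnca
Title: Noncompartmental Pharmacokinetics for Extended-Release Depot Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noncompartmental pharmacokinetic (NCA) analysis of sparse
    concentration-time data from extended-release depot formulations, with a
    synthetic study simulator. Computes the standard extravascular NCA
    parameter set (Cmax, Tmax, Tlast, lambda_z by best-adjusted-R2 terminal
    fit, half-life, AUC by the linear-up/log-down trapezoidal rule with
    extrapolation to infinity, apparent clearance, mean residence times) plus
    therapeutic-threshold onset and duration with log-linear extrapolation.
    Includes a dual-depot first-order absorption simulator with log-normal
    between-subject variability, proportional residual error, quantitation
    limit censoring, a first-order metabolite cascade, and species-preset
    liver-microsome depletion kinetics; group summaries, exact Mann-Whitney
    comparisons with Bonferroni adjustment, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    ggplot2,
    withr
Config/testthat/edition: 3
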