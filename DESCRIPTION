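Package: tickvax
Title: Stage-Structured Efficacy Analysis of Anti-Tick Cattle Vaccine Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-antigen, multi-tick-species cattle
    vaccination trials. Computes stage-wise tick reduction indices (engorgement,
    molting, oviposition, fertility), a significance-gated multiplicative
    vaccine-efficacy index over the tick life cycle, stage-coverage accounting,
    antibody-response (ELISA OD450) comparisons, and titer-outcome correlation
    with reduction-threshold detection. Includes a configurable synthetic-trial
    generator (beta-binomial stage chains, log-normal masses, prime/boost
    antibody dynamics) so every analysis stage is testable without raw trial
    data, plus readers/writers for the trial CSV schemas and a publication-style
    report generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
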