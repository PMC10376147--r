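Package: colibatch
Title: Mechanistic Batch Cultivation Modelling and Characterization of
    Glucose-Uptake Mutants of Escherichia coli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-based characterization of Escherichia coli
    strains in batch and glucose-pulse cultivations across microtiter
    plate, mini-bioreactor and stirred-tank platforms. Implements a
    macro-kinetic growth model with glucose partitioning, overflow
    metabolism and acetate recycling; gas-phase mass balances for oxygen
    uptake and carbon dioxide production rates with their inversion for
    in-silico data; a cumulative-OUR (Luedeking-Piret) biomass soft
    sensor; a synthetic multi-platform cultivation data generator; and
    multi-start weighted nonlinear least-squares parameter estimation
    with linearized uncertainties and profile-based identifiability
    diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    minpack.lm,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
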