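Package: epskinetics
Title: Growth and Product-Formation Kinetics for Microbial Exopolysaccharide Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing microbial fermentation time courses with the
    logistic growth model and the Luedeking-Piret product-formation model.
    Provides closed-form and rate-form model functions, two-stage nonlinear
    least-squares fitting (biomass first, product second) with multi-start
    initialisation and bootstrap confidence intervals, specific production
    rates and growth-association classification, a seeded synthetic-data
    generator emulating a replicated two-temperature shake-flask design,
    colorimetric assay arithmetic (phenol-sulfuric calibration curves and
    alpha-amylase inhibition rates), and a reproducible simulate-fit-report
    pipeline with CSV and JSON interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
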