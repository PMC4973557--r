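Package: phycoflux
Title: Dynamic Flux Balance Modeling of Stress-Induced Pigment Accumulation in Microalgae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic flux balance analysis (DFBA) of photoautotrophic growth and
    stress-induced beta-carotene accumulation in halotolerant green microalgae
    such as Dunaliella salina. Couples a stoichiometric flux balance core with
    lexicographic objectives and a phase-I infeasibility penalty to a Droop
    nitrogen-quota photobioreactor model with Lambert-Beer light attenuation.
    Regulatory submodels set state-dependent flux bounds for light supply,
    chlorophyll and beta-carotene accumulation, nitrate metabolization and a
    lag phase. Includes penalized least-squares parameter estimation with a
    differential-evolution optimizer, synthetic pseudo-experiment generation,
    and model-based fed-batch feed design with a two-factor design scan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    xml2,
    readr,
    DEoptim,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    withr
Config/testthat/edition: 3
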