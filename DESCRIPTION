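Package: szcea
Title: Cost-Utility Modelling of Antipsychotic Treatment Sequences in Schizophrenia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A semi-Markov cohort model for the cost-utility analysis of
    first-line antipsychotic strategies (lurasidone, olanzapine, risperidone)
    in schizophrenia from a healthcare-system perspective. Five health states
    (acute treatment trial, stable adherent, stable non-adherent, relapse,
    death) are simulated over a four-line treatment sequence with six-week
    cycles, parametric Weibull/Gompertz maintenance-phase hazards, excess
    mortality via standardized mortality ratios, and an irreversible diabetes
    prevalence overlay. Includes discounted cost and QALY valuation,
    incremental comparisons with dominance labelling and net monetary benefit,
    one-way sensitivity analysis with tornado ordering, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, a
    calibration module for baseline survival parameters and a synthetic life
    table, and an individual-level microsimulation oracle for verifying the
    cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
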