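Package: pmslt
Title: Proportional Multistate Life Table Projections of
    Overweight-Attributable Disease Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Projects incidence and mortality of non-communicable diseases
    attributable to overweight under counterfactual body-mass-index (BMI)
    scenarios, using a proportional multistate life table: a central cohort
    life table coupled to disease-specific illness-death life tables whose
    inflow is modified by potential impact fractions computed from shifting
    BMI distributions, with exposure-to-incidence lag times and Monte Carlo
    uncertainty intervals. Ships a self-consistent synthetic input generator
    emulating the Chilean adult population (ages 20-80, 2019-2030), the
    published relative-risk inputs and projection results as fixtures, and a
    reporting layer for attributable and averted burden.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
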