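Package: trsipm
Title: Incidence-Prevalence-Mortality Modelling of Treatment-Resistant
    Schizophrenia Prevalence
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the cross-sectional prevalence of
    treatment-resistant schizophrenia (TRS) with a four-state
    incidence-prevalence-mortality (IPM) Markov cohort model
    (Population, Schizophrenia, TRS, Dead) run over birth cohorts and
    aggregated at an index year.  Includes hazard-scale standardized
    mortality ratio adjustment, clozapine-based TRS proxy definitions,
    one-way sensitivity analysis over incidence and mortality inputs,
    a synthetic generator for cohort life tables, population pyramids
    and incidence schedules, and CSV readers and writers for all model
    inputs and outputs.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
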