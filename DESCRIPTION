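Package: dmburden
Title: Projecting the Burden of Type-2 Diabetes in an Aging Population
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for projecting the demographic, economic and mortality
    burden of type-2 diabetes among the elderly. Implements cohort-based
    estimation of age-specific prevalence, incidence and diabetic mortality
    from longitudinal survey data; a cohort-wise back/forward projection of
    the diabetic population with linear-growth doubling times and incidence
    scenario sweeps; two-part (participation times intensity) models of
    hospitalization and outpatient utilization with per-capita cost
    projection; Lee-Carter stochastic mortality forecasting; and abridged
    life tables with cause deletion and competing-risks hazard re-insertion
    yielding years of life lost to diabetes at age 60 with simulation-based
    confidence intervals. A synthetic-data module generates every input with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
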