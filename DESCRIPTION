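Package: mostscreen
Title: Factorial Screening Analysis for Intervention Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the optimization phase of the multiphase optimization
    strategy (MOST): full two-level factorial screening experiments on
    intervention components. Covers design enumeration and effect coding,
    screening-experiment sample size, simple randomization, scoring of the
    Beliefs about Medicines Questionnaire (necessity/concerns differential),
    data-quality (speed-responder) filters, effect-coded factorial regression
    with full and parsimonious fits, a stepped effect-hierarchy component
    screening decision engine with condition-level outcome prediction, a
    synthetic-cohort generator for end-to-end validation, and Monte-Carlo
    power, type-I and decision-accuracy simulations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
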