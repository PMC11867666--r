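Package: bictcea
Title: Cost-Effectiveness of Rapid Antimicrobial Susceptibility Testing for
    Hospital Urinary Tract Infections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A stratified hourly-cycle Markov cohort model evaluating a rapid
    (5-hour) bacterial impedance cytometry antimicrobial susceptibility test
    against standard (48-hour) urine culture for adult hospital inpatients
    with suspected urinary tract infection, from an NHS healthcare-system
    perspective. Provides a synthetic cohort generator emulating national
    admissions data, treatment-pathway and resistance-scenario registries,
    deterministic and analytic cohort propagation to absorption, economic
    outcomes (costs, QALYs, net monetary benefit, bed days, days on
    inappropriate antibiotics), univariate (tornado) sensitivity analysis,
    and probabilistic sensitivity analysis with cost-effectiveness plane and
    acceptability-curve outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
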