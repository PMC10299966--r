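Package: mortrans
Title: Five-Phase Maternal, Stillbirth, and Neonatal Mortality Transition Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies countries into the five phases of the combined
    maternal mortality, stillbirth, and neonatal mortality transition from
    dual mortality thresholds, quantifies movement between phases over time,
    profiles phase-specific covariates (fertility, causes of death, abortion
    policy, service coverage), computes wealth-quintile inequality statistics
    including the inequality patterns index, and ships a synthetic
    country-panel generator so the whole pipeline can be exercised and
    validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
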