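Package: thermoex
Title: Thermoregulatory and Sweat-Rate Analysis of Graded Treadmill Exercise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for thermoregulatory responses to graded
    (Bruce-protocol) treadmill exercise. Ingests breath-by-breath indirect
    calorimetry and ventilated-capsule perspiration traces, aggregates them to
    per-minute series, derives external workload, metabolic energy expenditure,
    heat production, metabolic efficiency and temperature-increment load,
    converts local sweat rates to whole-body rates and normalizes them by
    sweat-inducing factors, and compares constitutional groups per exercise
    minute with Kruskal-Wallis and Nemenyi post hoc tests under subject
    attrition. A synthetic-data module generates complete studies with the
    assumed statistical structure so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
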