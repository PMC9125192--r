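Package: psofa
Title: Pig-Specific Sequential Organ Failure Assessment Scoring for
    Experimental Sepsis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Severity quantification for porcine fecal-peritonitis sepsis
    models: a pig-specific Sequential Organ Failure Assessment (pSOFA)
    scoring engine in 3-domain and 5-domain forms, goal-directed
    supportive-therapy trigger rules, Sepsis-3-adapted severity
    classification (sepsis, septic shock, non-responder, fulminant),
    derived oxygen-transport and hemodynamic quantities, colony-forming
    unit quantification with inoculum severity bands, the rank-based
    statistical procedures used to relate microbial load and plasma
    biomarkers to organ dysfunction, and a synthetic minipig cohort
    generator for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
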