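Package: clinrules
Title: Association Rule Screening of Dichotomized Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exhaustive mining of one- and two-condition association rules
    (support, confidence, lift) against a fixed outcome item in small clinical
    cohorts, with dichotomization of continuous patient-reported outcome
    measures (fixed cut-offs and equal-frequency median splits), Fisher's
    exact or chi-squared testing of each rule's applicable/non-applicable
    2x2 table, single-versus-combined rule comparison, and a seeded synthetic
    knee-replacement cohort generator with plantable antecedent-outcome
    dependencies for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
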