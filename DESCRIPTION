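Package: icutriage
Title: Simulation of Tertiary Triage Policies in a Fully Occupied ICU
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate tertiary (ex post) intensive-care triage
    policies by Monte-Carlo simulation. Provides a calibrated synthetic
    electronic-health-record cohort generator, data preparation for raw
    patient exports (first severity scores, COVID-19 detection, length of
    stay, plausibility filtering), severity scoring (SAPS II-predicted
    mortality after Le Gall, a SAPS-to-SOFA scale adjustment, and an
    adjusted DIVI point score), the swap mechanics of ten score- and
    non-score-based triage policies, a scenario-based simulation study over
    a fully occupied 60-bed ICU, and summary plus ANOVA/Tukey-HSD
    comparison of the resulting ICU mortalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
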