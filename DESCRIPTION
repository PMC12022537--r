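Package: habitest
Title: Habituation-Aware Test-Retest Reliability Analysis for Repeated
    Neurocognitive Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies systematic error (learning and habituation effects)
    and random error (mean absolute error, mean absolute percentage error,
    Bland-Altman limits of agreement) alongside relative reliability
    (two-way absolute-agreement intraclass correlation with F-based
    confidence intervals, standard error of measurement, minimal detectable
    change) across repeated intraday and interday testing sessions.
    Detects the session after which performance has stabilized enough for
    valid testing, compares learning across age groups with mixed
    repeated-measures ANOVA and Scheffe post hoc contrasts, and ships a
    seeded synthetic-cohort generator with group-specific baselines,
    decaying learning effects and shrinking random error for simulation
    studies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
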