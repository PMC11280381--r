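Package: qsarlm
Title: Linear QSAR Modelling, Validation and Rule-Based Candidate Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits and validates two-dimensional quantitative structure-activity
    relationship (QSAR) models by multiple linear regression, following the
    workflow used for acetylcholinesterase-inhibitor design: correlation-based
    descriptor selection, seeded train/test splitting, ordinary least squares
    fitting with standardized coefficients, leave-one-out cross-validation
    (Q2), external validation, y-randomization with the cRp2 correction,
    variance inflation factors, a leverage-based applicability domain
    (Williams plot), activity prediction for designed candidates, and
    rule-based drug-likeness and pharmacokinetic gating (Lipinski, blood-brain
    barrier, CNS, ADMET thresholds). Includes a calibrated synthetic
    descriptor-table generator and in-paper candidate/ADMET fixtures so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    ChemmineR
Config/testthat/edition: 3
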