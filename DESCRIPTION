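Package: depscreen
Title: Staged Depression and Suicide-Risk Screening for General Medical Practices
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the two-stage depression and suicide-risk screening
    algorithm used in Hungarian general medical practices: a four-item Beck
    Hopelessness Scale (BHS-4) gate, a nine-item Beck Depression Inventory
    (BDI-9) stage with severity bands, and a DSM-5 major depressive episode
    check, under three cutoff protocols that differ in which BHS totals end
    screening. Classifies survey cohorts into care-need categories, tabulates
    counts and prevalences against the full-sample denominator, extrapolates
    category counts to target populations (an average 1,600-adult practice and
    the Hungarian 25+ population) with half-away-from-zero rounding, and
    generates seedable synthetic cohorts calibrated to published marginal
    structure so the whole pipeline is testable without the non-public survey
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
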