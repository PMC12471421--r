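Package: swinescore
Title: Pig-Specific Sepsis Severity Scoring for Conscious Swine Trauma Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Derivation of pig-specific SIRS thresholds and NEWS2 bands from
    baseline telemetry of healthy Yorkshire pigs (diurnal mean +/- 2 SD),
    scoring engines for SIRS, an adapted porcine SOFA (including the SNORT
    neurological rubric) and NEWS2, and an end-to-end cohort pipeline:
    8-hour window aggregation of telemetry, prevalence tables with death
    censoring, exact Mann-Whitney group comparison with Holm-Sidak
    correction, survival summaries, and a rule-based group classifier.
    Includes a synthetic cohort generator emulating a 72-hour conscious
    swine model of penetrating abdominal trauma with fecal peritonitis, so
    the full analysis is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
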