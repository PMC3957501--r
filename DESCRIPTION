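Package: staraudit
Title: Deduction-Based Audit Scoring of Clinical Case Notes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An audit engine for checklist-based scoring of clinical case
    note series. Implements the STAR (Surgical Tool for Auditing Records)
    instrument - six weighted sections, fifty essential items, one point
    deducted per missing item, with per-entry averaging for subsequent
    progress entries - together with the CRABEL comparator instrument,
    omission analytics, inter-rater reliability (Cronbach's alpha and mean
    inter-rater correlation), pre/post audit-cycle comparison via exact and
    approximate Mann-Whitney U tests, a seedable synthetic case-note
    generator with configurable per-item missingness, and JSON/CSV readers,
    writers and report renderers with a small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
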