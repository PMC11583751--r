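Package: bloodcdw
Title: Clinical Data Warehouse for Blood Transfusion Documentation Compliance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs blood-transfusion episodes from long-format
    electronic medical record (EMR) clinical-event extracts, scores each
    episode against the documentation measures of the Australian NSQHS
    Blood Management standard (consent, compatibility, completion, and the
    four-interval vital-sign observation schedule with grace periods), and
    maintains a two-granularity clinical data warehouse (event-level
    transfusion table plus a daily fact table) that feeds dashboard-style
    status and history views. Includes an incremental batch ETL with
    record-version invalidation semantics and a synthetic EMR extract
    simulator with ground truth for end-to-end testing without hospital
    data.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
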