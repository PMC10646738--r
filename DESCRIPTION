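Package: msbos
Title: Blood Utilization Audit and Maximum Surgical Blood Order Schedules
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for auditing preoperative red-blood-cell ordering in
    elective surgery. Computes the standard blood-bank utilization indices
    (cross-match-to-transfusion ratio, transfusion probability, transfusion
    index, non-usage probability, and wastage as a percentage of issue) from
    patient-level transfusion records, flags them against accepted efficiency
    thresholds, and derives a Maximum Surgical Blood Order Schedule (MSBOS)
    with per-procedure crossmatch versus type-and-screen recommendations.
    Includes a synthetic-cohort generator for validating audit pipelines
    without patient data, and a small command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
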