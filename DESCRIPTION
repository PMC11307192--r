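Package: chrtest
Title: Critical Speed and Critical Heart Rate Analysis for Timed Walking Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the field assessment of aerobic exercise intensity in
    people with Parkinson's disease from three timed walking efforts with
    continuous heart-rate recording. Fits the two-parameter critical-power
    model in its distance-time (critical speed) and heartbeats-time
    (critical heart rate) forms, computes per-effort metrics (total
    heartbeats, mean/maximal heart rate, duration validity), runs a
    test-retest reliability battery (typical error, coefficient of
    variation, intraclass correlation, standard error of measurement,
    minimal detectable change), analyses pre/post training effects with
    paired tests and effect-size bands, reproduces the cohort descriptive
    table, and simulates cohorts with known ground-truth parameters for
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
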