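Package: screentriage
Title: AI Triage Simulation for Mammography Screening Workflows
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate an artificial-intelligence risk score as a
    triage and second-reader mechanism in population mammography screening.
    Implements ROC construction with Youden-index threshold selection,
    green/yellow/red triage of screening visits with Table-2 style
    contingency summaries, prevalence-matched bootstrap construction of
    simulated cohorts at a target cancer rate, simulation of four reading
    workflows (double reading, AI second reader, hybrid flagged review, AI
    triage) with workload, detection, PPV1 and NPV accounting, and a
    longitudinal earlier-detection (lead-time) analysis of prior screening
    visits. Ships in-study fixtures and a synthetic cohort generator so the
    full pipeline runs without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
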