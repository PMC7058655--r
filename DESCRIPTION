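Package: bsikinetics
Title: Broken-Stick Kinetics of Acute-Phase Biomarkers Before Bloodstream Infection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the population-level kinetics of C-reactive protein (CRP)
    and plasma albumin (PA) in the 30 days preceding community-acquired
    bloodstream infection (CA-BSI). Provides a continuous two-segment
    ("broken-stick") regression estimator with a profiled change-point,
    patient-level percentile-bootstrap confidence intervals, bootstrap
    inference for parameter differences between microbial groups,
    detection-limit imputation and eligibility filtering for laboratory
    measurement series, per-patient two-window slope analysis, and a
    synthetic-cohort generator that emulates the sampling structure of
    hospital biomarker registries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
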