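Package: fedaudit
Title: Misconduct Simulation and Detection for Decentralized Federated
    Logistic Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates multi-site decentralized Newton-Raphson logistic
    regression (GLORE-style) in which each site exchanges per-iteration
    gradient vectors and information matrices, injects ten types of model
    misconduct (plagiarism, fabrication, falsification) into the resulting
    model traces, and detects the tampered submissions with three
    complementary detectors (Auditing, Coefficient, Performance) combined
    by OR, with greedy tuning of the ModelChange Ratio and AUC Difference
    Threshold. Includes synthetic clinical-dataset generators with
    prevalence calibration, three evaluation schemes (Iteration-Site,
    Iteration-Aggregated, Site-Aggregated) scored by per-trial 10-fold
    cross-validation, ablation utilities, and JSON-lines model-trace I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
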