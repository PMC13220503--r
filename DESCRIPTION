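Package: partsurv
Title: Partitioned-Survival Cost-Effectiveness Modelling from Digitised
    Kaplan-Meier Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pragmatic health-technology-appraisal pipeline for oncology
    biosimilars. Reconstructs pseudo-individual patient data from digitised
    Kaplan-Meier curves and numbers-at-risk tables, fits and ranks seven
    parametric survival distributions with hazard-shape diagnostics, runs a
    three-state (progression-free / progressed / dead) partitioned survival
    model with vial-based drug acquisition costing, computes discounted
    life-years, QALYs, costs, ICERs and incremental net monetary benefit with
    QALY-shortfall severity-modifier weighting, and supports deterministic
    scenario analyses and probabilistic sensitivity analysis. Includes a
    synthetic two-arm trial generator (with a simulated digitisation process)
    so the full pipeline runs end-to-end without access to confidential trial
    or price data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    flexsurv,
    survival,
    stats,
    utils,
    splines,
    MASS,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
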