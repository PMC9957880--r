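Package: chondrosim
Title: Discrete-Event Simulation of Knee Cartilage Repair Cost-Effectiveness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A patient-level discrete-event simulation of the lifetime
    cost-effectiveness of matrix-associated autologous chondrocyte
    implantation (M-ACI) for articular cartilage defects of the knee,
    from the perspective of German statutory health insurance. Generates
    synthetic patient cohorts from published marginal distributions,
    calibrates two-component Weibull time-to-failure models for each
    repair and replacement procedure from sparse survivorship anchors,
    simulates paired treatment trajectories with and without M-ACI under
    common random numbers, accrues quality-adjusted life years and costs
    with discounting, and computes incremental cost-effectiveness ratios,
    cost-effectiveness acceptability curves, and one-way tornado
    sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
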