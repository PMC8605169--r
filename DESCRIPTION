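Package: usigma
Title: Six Sigma Analytical Performance Evaluation and Risk-Based SQC
    Strategy Design for Urinary Biochemical Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes six sigma metrics for clinical laboratory assays from
    internal quality control (IQC) series and external quality assessment
    (EQA) replicates: coefficient of variation, percent bias against a
    peer-group target, sigma = (TEa - |bias|)/CV, defects per million, and
    the quality goal index (QGI). Selects risk-based statistical quality
    control strategies (Westgard sigma rules with run sizes), evaluates
    Westgard multirules on control data, draws normalized method decision
    charts, classifies improvement priorities from the QGI, and bundles the
    whole analysis into a one-command reproducible pipeline. A synthetic-data
    generator produces IQC/EQA fixtures with known true CV, bias and sigma
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
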