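#' Published five-laboratory evaluation tables
#'
#' Reference results from a published multicenter evaluation of the ten
#' routine urinary biochemical assays across five laboratories sharing one
#' analytical platform (2020 EQA cycle, national TEa goals). Three tables
#' are shipped as plain-text CSVs:
#'
#' * `fivelab_sigma()` — the reported sigma metric per laboratory, analyte
#'   and control level (100 values).
#' * `fivelab_strategies()` — the risk-based SQC strategy the evaluation
#'   adopted per laboratory and analyte (rules, N, run size; 50 cells).
#' * `fivelab_qgi()` — for the 20 assays below six sigma, both levels'
#'   sigma and QGI and the improvement priority.
#'
#' The underlying raw IQC/EQA data are not publicly deposited; these
#' derived values serve as reference anchors for validating
#' [select_strategy()] and [classify_improvement()] and for worked
#' examples.
#'
#' @return A tibble (see per-table columns above).
#' @name fivelab
NULL

fivelab_csv <- function(name) {
  readr::read_csv(system.file("extdata", name, package = "usigma",
                              mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname fivelab
#' @export
fivelab_sigma <- function() fivelab_csv("fivelab_sigma.csv")

#' @rdname fivelab
#' @export
fivelab_strategies <- function() fivelab_csv("fivelab_strategies.csv")

#' @rdname fivelab
#' @export
fivelab_qgi <- function() fivelab_csv("fivelab_qgi.csv")

#' Reconstruct (CV, bias) from reported sigma, QGI and TEa
#'
#' Sigma and QGI are two equations in the two unknowns CV and bias:
#' `sigma = (tea - bias) / cv` and `qgi = bias / (1.5 cv)` solve to
#' `cv = tea / (sigma + 1.5 qgi)` and `bias = 1.5 qgi cv`. Useful for
#' round-trip checks against published tables that print only the derived
#' values.
#'
#' @param sigma Reported sigma metric.
#' @param qgi_value Reported QGI.
#' @param tea_percent TEa goal (%).
#' @return Tibble with columns `cv` and `bias` (percent). Vectorized.
#' @export
invert_sigma_qgi <- function(sigma, qgi_value, tea_percent) {
  cv <- tea_percent / (sigma + 1.5 * qgi_value)
  tibble::tibble(cv = cv, bias = 1.5 * qgi_value * cv)
}
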