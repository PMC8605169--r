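#' Run the full six sigma evaluation pipeline
#'
#' One call from raw inputs to the complete analysis surface: per-assay
#' CV/bias/sigma/zone metrics, one risk-based SQC strategy per
#' `(lab, analyte)` (minimum-sigma policy), the QGI improvement table for
#' assays below six sigma, and normalized decision-chart coordinates.
#' IQC keys without an EQA counterpart (or vice versa) are reported in
#' `skipped_keys`, not fatal. Outputs are deterministic for fixed inputs.
#'
#' @param iqc_path Path to the IQC CSV (`lab,analyte,level,run,value`).
#' @param eqa_path Path to the EQA CSV
#'   (`lab,analyte,level,replicate,value,target`).
#' @param tea Path to a TEa JSON file or the builtin tag
#'   `"china_eqa_2020"`.
#' @param bias_convention Summary-bias convention, see [compute_bias()].
#' @param strict_n Required EQA replicate count (default 5; `NULL` to
#'   relax).
#' @param policy_table Sigma-band policy, see [westgard_policy()].
#' @return A list of class `usigma_report`: `metrics`, `strategies`,
#'   `improvement`, `chart_points`, `skipped_keys`, `provenance`.
#' @export
run_pipeline <- function(iqc_path, eqa_path, tea = "china_eqa_2020",
                         bias_convention = c("mean_then_abs",
                                             "abs_then_mean"),
                         strict_n = 5,
                         policy_table = westgard_policy()) {
  bias_convention <- match.arg(bias_convention)
  iqc <- read_iqc(iqc_path)
  eqa <- read_eqa(eqa_path, strict_n = strict_n)
  goals <- load_tea_goals(tea)

  metrics <- performance_table(iqc, eqa, goals,
                               bias_convention = bias_convention)
  strategies <- strategy_table(metrics, policy_table = policy_table)
  improvement <- improvement_table(metrics)
  chart_points <- normalize_points(metrics)

  provenance <- list(
    package = "usigma",
    version = as.character(utils::packageVersion("usigma")),
    inputs = list(
      iqc = list(path = iqc_path, sha256 = file_sha256(iqc_path)),
      eqa = list(path = eqa_path, sha256 = file_sha256(eqa_path)),
      tea = if (file.exists(tea)) {
        list(path = tea, sha256 = file_sha256(tea))
      } else {
        list(builtin = tea)
      }
    ),
    config = list(bias_convention = bias_convention,
                  strict_n = strict_n,
                  policy = "min",
                  run_sizes = stats::setNames(policy_table$run_size,
                                              policy_table$band))
  )
  structure(
    list(metrics = metrics, strategies = strategies,
         improvement = improvement, chart_points = chart_points,
         skipped_keys = attr(metrics, "skipped_keys"),
         provenance = provenance),
    class = "usigma_report"
  )
}

#' QGI improvement table for assays below six sigma
#'
#' One row per `(lab, analyte)` whose minimum-across-levels sigma is below
#' six, with both levels' sigma and QGI and the improvement label. When
#' the two levels' classifications agree the row carries the single label;
#' when they disagree both are reported, slash-joined, so a discrepancy is
#' never hidden. A level at or above six sigma contributes no QGI.
#'
#' @param metrics Performance table from [performance_table()].
#' @return Tibble: `lab`, `analyte`, `sigma_level1`, `sigma_level2`,
#'   `qgi_level1`, `qgi_level2`, `improvement`.
#' @export
improvement_table <- function(metrics) {
  wide <- metrics |>
    dplyr::select("lab", "analyte", "level", "sigma", "qgi",
                  "improvement") |>
    tidyr::pivot_wider(names_from = "level",
                       values_from = c("sigma", "qgi", "improvement"))
  lv <- sort(unique(metrics$level))
  sig_cols <- paste0("sigma_", lv)
  imp_cols <- paste0("improvement_", lv)
  keep <- do.call(pmin, c(wide[sig_cols], na.rm = TRUE)) < 6
  wide <- wide[keep, , drop = FALSE]
  wide$improvement <- vapply(seq_len(nrow(wide)), function(i) {
    cl <- unlist(wide[i, imp_cols])
    cl <- cl[!is.na(cl) & cl != "none"]
    paste(unique(improvement_label(cl)), collapse = " / ")
  }, character(1))
  wide[c("lab", "analyte", sig_cols, paste0("qgi_", lv), "improvement")]
}

#' @export
print.usigma_report <- function(x, ...) {
  cat("usigma report\n")
  cat("  assays evaluated :", nrow(x$metrics), "lab/analyte/level records\n")
  cat("  SQC strategies   :", nrow(x$strategies), "lab/analyte pairs\n")
  cat("  below six sigma  :", nrow(x$improvement), "assays need improvement\n")
  if (nrow(x$skipped_keys)) {
    cat("  skipped keys     :", nrow(x$skipped_keys),
        "(no matching counterpart)\n")
  }
  invisible(x)
}

#' Write a report to disk
#'
#' Writes `metrics.csv`, `strategies.csv`, `improvement.csv`, the two
#' decision charts (`level1.svg`, `level2.svg`, one per control level
#' present), `report.md` with the same tables in human-readable form,
#' `metrics.json` at full precision, and `provenance.json` (input SHA-256
#' digests, configuration, package version). CSV floats are rounded
#' half-even to two decimals, matching reporting practice; JSON keeps full
#' precision. Identical inputs produce byte-identical files.
#'
#' @param report A `usigma_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
render_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  round2 <- function(df) {
    dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                    \(x) round(x, 2)))
  }
  metrics_out <- round2(dplyr::mutate(report$metrics,
                                      zone = as.character(.data$zone)))
  p <- file.path(out_dir, "metrics.csv")
  readr::write_csv(metrics_out, p, na = "")
  paths <- c(paths, p)

  p <- file.path(out_dir, "strategies.csv")
  readr::write_csv(round2(report$strategies), p)
  paths <- c(paths, p)

  p <- file.path(out_dir, "improvement.csv")
  readr::write_csv(round2(report$improvement), p, na = "")
  paths <- c(paths, p)

  for (lv in sort(unique(report$chart_points$level))) {
    p <- file.path(out_dir, paste0(lv, ".svg"))
    render_chart(report$chart_points[report$chart_points$level == lv, ],
                 lv, p)
    paths <- c(paths, p)
  }

  p <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(report$metrics, p, dataframe = "rows", digits = NA,
                       na = "null", pretty = TRUE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(report$provenance, p, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "report.md")
  writeLines(report_markdown(report, metrics_out), p)
  paths <- c(paths, p)

  invisible(paths)
}

report_markdown <- function(report, metrics_out) {
  md_table <- function(df) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::everything(),
                                          \(x) {
                                            out <- as.character(x)
                                            out[is.na(out)] <- ""
                                            out
                                          }))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1, \(r) paste0("| ", paste(r, collapse = " | "), " |"))
    c(header, sep, rows)
  }
  out <- c(
    "# Six sigma evaluation report",
    "",
    "## Sigma metrics by assay and control level",
    "",
    md_table(metrics_out),
    "",
    "## Risk-based SQC strategies (minimum-sigma policy)",
    "",
    md_table(dplyr::mutate(report$strategies,
                           effective_sigma = round(.data$effective_sigma, 2))),
    "",
    "## Improvement priorities (assays below six sigma)",
    ""
  )
  if (nrow(report$improvement)) {
    imp <- dplyr::mutate(report$improvement,
                         dplyr::across(dplyr::where(is.numeric),
                                       \(x) round(x, 2)))
    out <- c(out, md_table(imp))
  } else {
    out <- c(out, "All assays at or above six sigma; no improvement needed.")
  }
  if (nrow(report$skipped_keys)) {
    out <- c(out, "", "## Skipped keys (missing counterpart)", "",
             md_table(report$skipped_keys))
  }
  out
}

file_sha256 <- function(path) {
  digest::digest(file = path, algo = "sha256")
}

#' Recompute sigma from a supplementary per-lab CV/bias table, if present
#'
#' The five-laboratory study's raw per-assay CV and bias live in a
#' supplementary table that is not publicly deposited. If a CSV export of
#' it (columns `lab,analyte,level,cv,bias`) is available, this recomputes
#' each sigma from the goals table; otherwise it reports the check as
#' skipped rather than failing.
#'
#' @param path Path to the supplementary CSV, or `NULL` if unavailable.
#' @param goals TEa goal table.
#' @return A list with `status` (`"ok"` or `"skipped"`) and, when run, a
#'   tibble `sigma` of recomputed values.
#' @export
check_supplementary_sigma <- function(path = NULL,
                                      goals = load_tea_goals()) {
  if (is.null(path) || !file.exists(path)) {
    return(list(status = "skipped",
                reason = "supplementary CV/bias table not available"))
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  df$sigma <- sigma_metric(tea_for(goals, df$analyte), df$bias, df$cv)
  list(status = "ok", sigma = df)
}
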