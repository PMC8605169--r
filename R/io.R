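#' Read internal QC (IQC) measurement series
#'
#' Reads a long-format CSV of internal QC measurements (one measurement per
#' row) and groups it into one series per `(lab, analyte, level)` key.
#' Rows within a series are sorted by run identifier (ties keep file
#' order), so unordered exports are accepted.
#'
#' @param path Path to a CSV with header `lab,analyte,level,run,value`.
#' @param dialect Optional named character vector remapping non-standard
#'   column names, e.g. `c(lab = "site")` when the file calls the lab
#'   column `site`.
#' @return A nested tibble of class `usigma_iqc`: one row per series with
#'   columns `lab`, `analyte`, `level`, `run` (list), `values` (list), `n`.
#' @export
read_iqc <- function(path, dialect = NULL) {
  df <- read_measurement_csv(path, c("lab", "analyte", "level", "run", "value"),
                             dialect)
  bad <- which(!is.finite(df$value) | df$value <= 0)
  if (length(bad)) {
    stop("IQC values must be positive and finite; first offending data row: ",
         bad[1], " (value = ", df$value[bad[1]], ")", call. = FALSE)
  }
  out <- df |>
    dplyr::mutate(.file_order = dplyr::row_number()) |>
    dplyr::group_by(.data$lab, .data$analyte, .data$level) |>
    dplyr::arrange(.data$run, .data$.file_order, .by_group = TRUE) |>
    dplyr::summarise(
      run = list(.data$run),
      values = list(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n < 2)) {
    k <- out[out$n < 2, c("lab", "analyte", "level")]
    stop("IQC series must hold at least 2 values; offending key(s): ",
         paste(do.call(paste, c(k, sep = "/")), collapse = ", "),
         call. = FALSE)
  }
  class(out) <- c("usigma_iqc", class(out))
  out
}

#' Write IQC series back to long-format CSV
#'
#' Inverse of [read_iqc()]: a written file re-reads to an identical
#' collection.
#'
#' @param iqc A `usigma_iqc` nested tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_iqc <- function(iqc, path) {
  long <- tidyr::unnest(iqc[c("lab", "analyte", "level", "run", "values")],
                        cols = c("run", "values"))
  names(long)[names(long) == "values"] <- "value"
  readr::write_csv(long, path)
  invisible(path)
}

#' Read EQA replicate sets
#'
#' Reads a long-format CSV of external quality assessment replicate
#' measurements and groups it into one replicate set per
#' `(lab, analyte, level)` key. Each set carries the peer-group target
#' value, which must be constant within a key.
#'
#' @param path Path to a CSV with header
#'   `lab,analyte,level,replicate,value,target`.
#' @param strict_n Required replicate count (default 5, the usual
#'   same-batch EQA protocol). Set `NULL` to accept any n >= 2.
#' @param dialect Optional named character vector remapping column names.
#' @return A nested tibble of class `usigma_eqa`: one row per set with
#'   columns `lab`, `analyte`, `level`, `replicates` (list), `target`, `n`.
#' @export
read_eqa <- function(path, strict_n = 5, dialect = NULL) {
  df <- read_measurement_csv(
    path, c("lab", "analyte", "level", "replicate", "value", "target"),
    dialect)
  out <- df |>
    dplyr::group_by(.data$lab, .data$analyte, .data$level) |>
    dplyr::arrange(.data$replicate, .by_group = TRUE) |>
    dplyr::summarise(
      replicates = list(.data$value),
      n_targets = dplyr::n_distinct(.data$target),
      target = .data$target[1],
      n = dplyr::n(),
      .groups = "drop"
    )
  if (any(out$n_targets > 1)) {
    k <- out[out$n_targets > 1, c("lab", "analyte", "level")]
    stop("inconsistent EQA target within key(s): ",
         paste(do.call(paste, c(k, sep = "/")), collapse = ", "),
         call. = FALSE)
  }
  out$n_targets <- NULL
  if (any(out$target <= 0 | !is.finite(out$target))) {
    stop("EQA target values must be positive", call. = FALSE)
  }
  if (any(out$n < 2)) {
    stop("EQA replicate sets need at least 2 replicates", call. = FALSE)
  }
  if (!is.null(strict_n) && any(out$n != strict_n)) {
    k <- out[out$n != strict_n, c("lab", "analyte", "level", "n")]
    stop("expected exactly ", strict_n, " EQA replicates per key; got: ",
         paste(do.call(paste, c(k, sep = "/")), collapse = ", "),
         " (set strict_n = NULL to accept)", call. = FALSE)
  }
  class(out) <- c("usigma_eqa", class(out))
  out
}

#' Write EQA replicate sets back to long-format CSV
#'
#' @param eqa A `usigma_eqa` nested tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eqa <- function(eqa, path) {
  long <- eqa |>
    dplyr::mutate(replicate = lapply(.data$n, seq_len)) |>
    dplyr::select("lab", "analyte", "level", "replicate",
                  value = "replicates", "target") |>
    tidyr::unnest(cols = c("replicate", "value"))
  readr::write_csv(long, path)
  invisible(path)
}

# Shared CSV reader: header check with named-column errors, dialect remap.
read_measurement_csv <- function(path, required, dialect = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      names(df)[names(df) == dialect[[std]]] <- std
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[required]
}
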