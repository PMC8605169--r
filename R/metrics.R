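#' Coefficient of variation from an IQC series
#'
#' Imprecision estimate: sample standard deviation (n - 1 denominator)
#' divided by the mean of the series, times 100. No outlier exclusion is
#' applied; the series' own mean is the reference.
#'
#' @param values Numeric vector of control measurements (one series), or a
#'   one-row `usigma_iqc` tibble.
#' @return CV as a percent. A series whose values are all identical
#'   returns 0 with a warning (zero-variance flag).
#' @examples
#' compute_cv(c(9, 10, 11))  # SD 1, mean 10 -> 10%
#' @export
compute_cv <- function(values) {
  if (inherits(values, "usigma_iqc")) {
    stopifnot(nrow(values) == 1L)
    values <- values$values[[1]]
  }
  values <- as.numeric(values)
  if (length(values) < 2) {
    stop("need at least 2 values to estimate a CV", call. = FALSE)
  }
  m <- mean(values)
  if (!is.finite(m) || m <= 0) {
    stop("series mean must be positive to express CV in percent",
         call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero-variance series: CV is 0", call. = FALSE)
    return(0)
  }
  100 * s / m
}

#' Percent bias from an EQA replicate set
#'
#' Each replicate's signed percent difference from the peer-group target is
#' `(measured - target) / target * 100`. The summary bias used in the sigma
#' metric is, under the default convention, the absolute value of the mean
#' signed difference (`mean_then_abs`); `abs_then_mean` averages the
#' absolute per-replicate differences instead. The two agree whenever all
#' replicates deviate in the same direction.
#'
#' @param replicates Numeric vector of replicate measurements, or a
#'   one-row `usigma_eqa` tibble (then `target` is taken from it).
#' @param target Peer-group target value (> 0).
#' @param convention `"mean_then_abs"` (default) or `"abs_then_mean"`.
#' @return A list of class `bias_result` with elements
#'   `per_replicate_bias_percent` (signed) and `bias_percent`
#'   (non-negative summary).
#' @examples
#' compute_bias(c(10.2, 10.1, 10.3, 10.2, 10.2), 10)$bias_percent  # 2.0
#' @export
compute_bias <- function(replicates, target,
                         convention = c("mean_then_abs", "abs_then_mean")) {
  convention <- match.arg(convention)
  if (inherits(replicates, "usigma_eqa")) {
    stopifnot(nrow(replicates) == 1L)
    target <- replicates$target
    replicates <- replicates$replicates[[1]]
  }
  if (!is.finite(target) || target <= 0) {
    stop("EQA target must be positive", call. = FALSE)
  }
  per <- (as.numeric(replicates) - target) / target * 100
  summary_bias <- switch(convention,
    mean_then_abs = abs(mean(per)),
    abs_then_mean = mean(abs(per))
  )
  structure(
    list(per_replicate_bias_percent = per, bias_percent = summary_bias,
         convention = convention),
    class = "bias_result"
  )
}

#' @export
print.bias_result <- function(x, ...) {
  cat("EQA bias:", format(x$bias_percent, digits = 4), "% (",
      x$convention, ", n = ", length(x$per_replicate_bias_percent),
      ")\n", sep = "")
  invisible(x)
}

#' Six sigma metric
#'
#' `sigma = (TEa - |bias|) / CV`, all three in percent: the number of
#' analytical standard deviations that fit between current performance and
#' the total allowable error goal. The value is not clamped — a bias
#' exceeding the goal yields a negative sigma.
#'
#' @param tea_percent Total allowable error goal (%).
#' @param bias_percent Bias (%); its absolute value is used.
#' @param cv_percent Imprecision (%); must be >= 0. A zero CV returns
#'   `Inf` with a warning rather than an error.
#' @return Sigma (dimensionless). Vectorized over all three arguments.
#' @examples
#' sigma_metric(20, 0, 20 / 6)  # 6
#' @export
sigma_metric <- function(tea_percent, bias_percent, cv_percent) {
  if (any(cv_percent < 0, na.rm = TRUE)) {
    stop("CV cannot be negative", call. = FALSE)
  }
  out <- (tea_percent - abs(bias_percent)) / cv_percent
  if (any(cv_percent == 0, na.rm = TRUE)) {
    warning("zero CV: sigma reported as infinite", call. = FALSE)
    out[cv_percent == 0] <- Inf
  }
  out
}

#' Defects per million at a sigma level
#'
#' Converts a sigma level to the long-run defect rate under the
#' conventional 1.5-sigma shift: the one-sided standard-normal upper tail
#' beyond `sigma - 1.5`, per million. Six sigma corresponds to 3.4 defects
#' per million, the "world-class" benchmark.
#'
#' @param sigma Sigma level(s), finite.
#' @return Defects per million (numeric, same length as `sigma`).
#' @examples
#' round(sigma_to_dpm(6), 1)  # 3.4
#' @export
sigma_to_dpm <- function(sigma) {
  1e6 * stats::pnorm(sigma - 1.5, lower.tail = FALSE)
}

#' Quality goal index (QGI)
#'
#' `QGI = bias / (1.5 * CV)`: the ratio of the trueness problem to the
#' imprecision problem. Used only for assays below six sigma to decide
#' which to improve first (see [classify_improvement()]).
#'
#' @param bias_percent Bias (%); absolute value is used.
#' @param cv_percent Imprecision (%), strictly positive.
#' @return QGI (non-negative, dimensionless). Vectorized.
#' @export
qgi <- function(bias_percent, cv_percent) {
  if (any(!is.finite(cv_percent) | cv_percent <= 0)) {
    stop("QGI requires a strictly positive CV", call. = FALSE)
  }
  abs(bias_percent) / (1.5 * cv_percent)
}

#' Improvement priority from sigma and QGI
#'
#' Assays at or above six sigma need no improvement. Below six sigma the
#' QGI decides: below 0.8 the dominant problem is imprecision; above 1.2
#' it is trueness; between 0.8 and 1.2 (inclusive) both need attention.
#'
#' @param sigma Sigma metric(s).
#' @param qgi_value QGI value(s); may be `NA` where `sigma >= 6`.
#' @return Character vector with levels `"none"`, `"imprecision"`,
#'   `"trueness"`, `"both"`.
#' @seealso [improvement_label()] for report-style display labels.
#' @export
classify_improvement <- function(sigma, qgi_value) {
  n <- max(length(sigma), length(qgi_value))
  sigma <- rep_len(sigma, n)
  qgi_value <- rep_len(qgi_value, n)
  out <- character(n)
  high <- sigma >= 6
  out[high] <- "none"
  q <- qgi_value[!high]
  if (anyNA(q)) {
    stop("QGI must be supplied wherever sigma < 6", call. = FALSE)
  }
  out[!high] <- ifelse(q < 0.8, "imprecision",
                       ifelse(q > 1.2, "trueness", "both"))
  out
}

#' Display label for an improvement class
#'
#' @param class Character vector of improvement classes from
#'   [classify_improvement()].
#' @return Report-style labels: `"Imprecision"`, `"Trueness"`,
#'   `"Imprecision and trueness"`, `"None"`.
#' @export
improvement_label <- function(class) {
  map <- c(none = "None", imprecision = "Imprecision",
           trueness = "Trueness", both = "Imprecision and trueness")
  unknown <- setdiff(unique(class), names(map))
  if (length(unknown)) {
    stop("unknown improvement class: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(map[class])
}

#' Per-assay performance table from IQC, EQA and TEa inputs
#'
#' Joins IQC series and EQA replicate sets on `(lab, analyte, level)`,
#' computes CV, bias, sigma, DPM, sigma zone, QGI (only where sigma < 6)
#' and the improvement class, one row per key. IQC keys without an EQA
#' counterpart (or vice versa) are dropped and listed in the
#' `skipped_keys` attribute rather than raising an error.
#'
#' @param iqc A `usigma_iqc` collection ([read_iqc()]).
#' @param eqa A `usigma_eqa` collection ([read_eqa()]).
#' @param goals A `tea_goals` table ([load_tea_goals()]).
#' @param bias_convention Passed to [compute_bias()].
#' @return A tibble with one row per `(lab, analyte, level)`: `cv`, `bias`,
#'   `tea`, `sigma`, `dpm`, `zone`, `qgi` (NA at or above six sigma),
#'   `improvement`.
#' @export
performance_table <- function(iqc, eqa, goals = load_tea_goals(),
                              bias_convention = c("mean_then_abs",
                                                  "abs_then_mean")) {
  bias_convention <- match.arg(bias_convention)
  key <- c("lab", "analyte", "level")
  matched <- dplyr::inner_join(
    iqc[c(key, "values")],
    eqa[c(key, "replicates", "target")],
    by = key
  )
  only_iqc <- dplyr::anti_join(iqc[key], eqa[key], by = key)
  only_eqa <- dplyr::anti_join(eqa[key], iqc[key], by = key)
  skipped <- dplyr::bind_rows(
    dplyr::mutate(only_iqc, missing = "eqa"),
    dplyr::mutate(only_eqa, missing = "iqc")
  )

  out <- matched |>
    dplyr::mutate(
      cv = purrr::map_dbl(.data$values, compute_cv),
      bias = purrr::map2_dbl(
        .data$replicates, .data$target,
        function(r, t) compute_bias(r, t, bias_convention)$bias_percent),
      tea = tea_for(goals, .data$analyte)
    ) |>
    dplyr::mutate(
      sigma = sigma_metric(.data$tea, .data$bias, .data$cv),
      dpm = sigma_to_dpm(.data$sigma),
      zone = sigma_band(.data$sigma),
      qgi = {
        q <- rep(NA_real_, length(.data$sigma))
        low <- .data$sigma < 6
        q[low] <- qgi(.data$bias[low], .data$cv[low])
        q
      },
      improvement = classify_improvement(.data$sigma, .data$qgi)
    ) |>
    dplyr::select(-"values", -"replicates", -"target")
  attr(out, "skipped_keys") <- skipped
  attr(out, "bias_convention") <- bias_convention
  out
}
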