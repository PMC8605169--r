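#' Westgard sigma-rules policy table
#'
#' The mapping from sigma band to SQC design used by [select_strategy()]:
#' which Westgard control rules to run, the total number of control
#' measurements N per QC event (two control materials), how many QC events
#' per analytical run, and the run size (patient samples between QC
#' events). The two top bands follow the worked sigma-rules flowchart
#' directly; the sub-four-sigma bands follow the published Westgard
#' sigma-rules convention (full multirule, N = 4, shrinking run sizes, and
#' a maximum-QC flag below three sigma) and can be overridden.
#'
#' @param overrides Optional named list of rows to replace, keyed by band
#'   label, each a list with any of `rules` (character vector),
#'   `n_controls`, `events`, `run_size`, `max_qc`.
#' @return Tibble with columns `band`, `rules` (list), `n_controls`,
#'   `events`, `run_size`, `max_qc`.
#' @export
westgard_policy <- function(overrides = NULL) {
  pol <- tibble::tibble(
    band = SIGMA_ZONES,
    rules = list(
      c("1_3s"),
      c("1_3s", "2_2s", "R_4s"),
      c("1_3s", "2_2s", "R_4s", "4_1s"),
      c("1_3s", "2_2s", "R_4s", "4_1s", "8_x"),
      c("1_3s", "2_2s", "R_4s", "4_1s", "8_x"),
      c("1_3s", "2_2s", "R_4s", "4_1s", "8_x")
    ),
    n_controls = c(2L, 2L, 4L, 4L, 4L, 4L),
    events = c(1L, 1L, 1L, 1L, 2L, 2L),
    run_size = c(1000L, 450L, 200L, 45L, 23L, 23L),
    max_qc = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
  if (!is.null(overrides)) {
    for (band in names(overrides)) {
      i <- match(band, pol$band)
      if (is.na(i)) stop("unknown sigma band: ", band, call. = FALSE)
      o <- overrides[[band]]
      if (!is.null(o$rules)) pol$rules[[i]] <- o$rules
      for (f in c("n_controls", "events", "run_size", "max_qc")) {
        if (!is.null(o[[f]])) pol[[f]][i] <- o[[f]]
      }
    }
  }
  pol
}

#' Select a risk-based SQC strategy from sigma values
#'
#' Applies the Westgard sigma-rules flowchart: the assay's effective sigma
#' (by default the minimum across its control levels — the conservative
#' choice) picks a sigma band, and the band determines the control rules,
#' N, QC events and run size. For example, sigma 5.94/5.97 yields the
#' 1_3s/2_2s/R_4s multirule with N = 2 and a run size of 450 samples,
#' while 7.14/7.46 needs only the single 1_3s rule with N = 2 and a run
#' size of 1000.
#'
#' @param sigma_by_level Named (or unnamed) numeric vector of sigma values,
#'   one per control level.
#' @param policy `"min"` (default) to use the minimum across levels, or
#'   `"per_level"` to return one strategy per level.
#' @param policy_table Band-to-design mapping, see [westgard_policy()].
#' @return A list of class `sqc_strategy` (`rules`, `n_controls`, `events`,
#'   `run_size`, `band`, `max_qc`, `effective_sigma`), or a list of such
#'   objects for `policy = "per_level"`.
#' @examples
#' select_strategy(c(level1 = 5.94, level2 = 5.97))$run_size  # 450
#' @export
select_strategy <- function(sigma_by_level, policy = c("min", "per_level"),
                            policy_table = westgard_policy()) {
  policy <- match.arg(policy)
  sigma_by_level <- sigma_by_level[is.finite(sigma_by_level) |
                                     is.infinite(sigma_by_level)]
  if (!length(sigma_by_level) || all(is.na(sigma_by_level))) {
    stop("at least one sigma value is required", call. = FALSE)
  }
  if (policy == "per_level") {
    return(lapply(sigma_by_level, select_strategy, policy = "min",
                  policy_table = policy_table))
  }
  eff <- min(sigma_by_level, na.rm = TRUE)
  band <- as.character(sigma_band(eff))
  i <- match(band, policy_table$band)
  structure(
    list(
      rules = policy_table$rules[[i]],
      n_controls = policy_table$n_controls[i],
      events = policy_table$events[i],
      run_size = policy_table$run_size[i],
      band = band,
      max_qc = policy_table$max_qc[i],
      effective_sigma = eff
    ),
    class = "sqc_strategy"
  )
}

#' @export
print.sqc_strategy <- function(x, ...) {
  cat(sprintf("SQC strategy [%s, effective sigma %.2f]: %s with N=%d and R=%d%s\n",
              x$band, x$effective_sigma, paste(x$rules, collapse = "/"),
              x$n_controls, x$run_size,
              if (x$max_qc) " (maximum QC; method improvement required)" else ""))
  invisible(x)
}

#' Strategy table for every assay in a performance table
#'
#' One strategy per `(lab, analyte)`, from the minimum sigma across that
#' assay's control levels.
#'
#' @param metrics Performance table from [performance_table()] (needs
#'   `lab`, `analyte`, `level`, `sigma`).
#' @param policy_table See [westgard_policy()].
#' @return Tibble: `lab`, `analyte`, `effective_sigma`, `band`, `rules`
#'   (slash-joined string), `n_controls`, `events`, `run_size`, `max_qc`.
#' @export
strategy_table <- function(metrics, policy_table = westgard_policy()) {
  metrics |>
    dplyr::group_by(.data$lab, .data$analyte) |>
    dplyr::summarise(
      strategy = list(select_strategy(.data$sigma,
                                      policy_table = policy_table)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      effective_sigma = purrr::map_dbl(.data$strategy, "effective_sigma"),
      band = purrr::map_chr(.data$strategy, "band"),
      rules = purrr::map_chr(.data$strategy,
                             \(s) paste(s$rules, collapse = "/")),
      n_controls = purrr::map_int(.data$strategy, "n_controls"),
      events = purrr::map_int(.data$strategy, "events"),
      run_size = purrr::map_int(.data$strategy, "run_size"),
      max_qc = purrr::map_lgl(.data$strategy, "max_qc")
    ) |>
    dplyr::select(-"strategy")
}

#' QC run series for multirule evaluation
#'
#' Bundles control observations with the established mean and SD of each
#' control material, the substrate for [evaluate_rules()].
#'
#' @param observations Tibble with columns `run` (sortable run index),
#'   `level` (control material tag), `value`.
#' @param limits Tibble with columns `level`, `mean`, `sd` (established
#'   target and SD per material; `sd` > 0).
#' @return List of class `qc_run_series`.
#' @export
qc_run_series <- function(observations, limits) {
  stopifnot(all(c("run", "level", "value") %in% names(observations)),
            all(c("level", "mean", "sd") %in% names(limits)))
  if (any(limits$sd <= 0)) stop("established SD must be > 0", call. = FALSE)
  missing <- setdiff(unique(observations$level), limits$level)
  if (length(missing)) {
    stop("no limits for level(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(observations = tibble::as_tibble(observations),
                 limits = tibble::as_tibble(limits)),
            class = "qc_run_series")
}

WESTGARD_RULES <- c("1_3s", "2_2s", "R_4s", "4_1s", "8_x")

#' Evaluate Westgard multirules on control data
#'
#' Z-scores each observation against its material's established mean/SD
#' and applies the selected rules run by run. Counting rules (2_2s, 4_1s,
#' 8_x) look at consecutive observations ordered within a run by material
#' level and then across runs; R_4s is a within-run range rule. Limits are
#' exceeded strictly (z > 2, not >= 2). A run is rejected iff at least one
#' selected rule fires in it.
#'
#' Rule semantics: 1_3s — any |z| > 3; 2_2s — two consecutive z on the
#' same side beyond 2 SD; R_4s — within one run, one observation above +2
#' and one below -2 (range > 4 SD); 4_1s — four consecutive on the same
#' side beyond 1 SD; 8_x — eight consecutive on the same side of the mean.
#'
#' @param series A [qc_run_series()].
#' @param strategy An `sqc_strategy` from [select_strategy()], or a
#'   character vector of rule codes.
#' @return Tibble with one row per run: `run`, `violated_rules` (list of
#'   character), `decision` (`"accept"` / `"reject"`).
#' @export
evaluate_rules <- function(series, strategy) {
  rules <- if (inherits(strategy, "sqc_strategy")) strategy$rules
           else as.character(strategy)
  unknown <- setdiff(rules, WESTGARD_RULES)
  if (length(unknown)) {
    stop("unknown control rule code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  obs <- series$observations
  ord <- order(obs$run, obs$level)
  obs <- obs[ord, ]
  i <- match(obs$level, series$limits$level)
  z <- (obs$value - series$limits$mean[i]) / series$limits$sd[i]
  runs <- obs$run
  n <- length(z)

  fires <- list()  # rule -> logical vector over observation positions
  if ("1_3s" %in% rules) fires[["1_3s"]] <- abs(z) > 3
  if ("2_2s" %in% rules) {
    f <- rep(FALSE, n)
    if (n >= 2) {
      idx <- 2:n
      f[idx] <- (z[idx] > 2 & z[idx - 1] > 2) |
                (z[idx] < -2 & z[idx - 1] < -2)
    }
    fires[["2_2s"]] <- f
  }
  if ("4_1s" %in% rules) fires[["4_1s"]] <- consecutive_beyond(z, 4, 1)
  if ("8_x" %in% rules) fires[["8_x"]] <- consecutive_beyond(z, 8, 0)

  run_ids <- unique(runs)
  run_f <- factor(runs, levels = run_ids)
  # run-level violation matrix (vectorized so long series stay fast)
  per_run <- lapply(fires, function(f) {
    rowsum(as.integer(f), run_f, reorder = FALSE)[, 1] > 0
  })
  if ("R_4s" %in% rules) {
    counts <- tabulate(run_f)
    mx <- vapply(split(z, run_f), max, numeric(1))
    mn <- vapply(split(z, run_f), min, numeric(1))
    per_run[["R_4s"]] <- counts >= 2 & mx > 2 & mn < -2 & (mx - mn) > 4
  }
  per_run <- per_run[intersect(rules, names(per_run))]
  mat <- do.call(cbind, per_run)
  viol_by_run <- unname(apply(mat, 1, function(r) names(per_run)[r],
                              simplify = FALSE))
  tibble::tibble(
    run = run_ids,
    violated_rules = viol_by_run,
    decision = ifelse(lengths(viol_by_run) > 0, "reject", "accept")
  )
}

# Positions where the trailing k observations all sit strictly beyond
# +limit or all strictly below -limit.
consecutive_beyond <- function(z, k, limit) {
  n <- length(z)
  f <- rep(FALSE, n)
  if (n < k) return(f)
  above <- z > limit
  below <- z < -limit
  ca <- cumsum(above)
  cb <- cumsum(below)
  idx <- k:n
  f[idx] <- (ca[idx] - c(0, ca)[idx - k + 1] == k) |
            (cb[idx] - c(0, cb)[idx - k + 1] == k)
  f
}

#' Number of QC events needed for a day's workload
#'
#' @param run_size Patient samples allowed between QC events.
#' @param daily_sample_count Patient samples expected in the day.
#' @return Integer count of QC events, `ceiling(daily / run_size)`.
#' @examples
#' schedule_qc(450, 900)  # 2
#' @export
schedule_qc <- function(run_size, daily_sample_count) {
  stopifnot(run_size >= 1, daily_sample_count >= 1)
  as.integer(ceiling(daily_sample_count / run_size))
}
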