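# Plausible urinary concentrations per analyte for the two control levels
# (level 1 ~ normal, level 2 ~ elevated). Units are nominal (mmol/L for
# electrolytes/metabolites, g/L for proteins); every downstream statistic
# is percent-based, so units never enter any computation.
ANALYTE_LEVEL_MEANS <- tibble::tibble(
  analyte = rep(c("K", "Na", "Cl", "Ca", "P", "GLU", "Urea", "Crea",
                  "TP", "mALB"), each = 2),
  level = rep(c("level1", "level2"), times = 10),
  true_mean = c(25, 55, 80, 180, 85, 190, 2.5, 6.0, 15, 35, 3, 15,
                150, 350, 6, 15, 0.08, 0.60, 0.02, 0.15)
)

#' Scenario grid emulating a five-laboratory urinary biochemistry study
#'
#' Builds the default synthetic study design: 5 laboratories x 10 urinary
#' analytes x 2 control levels (100 scenarios), with known true CV, bias
#' and hence true sigma. True sigma values span roughly 4 to 18 across the
#' grid — the range a multicenter evaluation of these assays on a shared
#' platform actually exhibits — and the bias-to-CV ratio cycles through
#' 0.5, 1, 2 and 3 so that every improvement class occurs. Each scenario
#' records 360 IQC values (two per day over six months) and a 5-replicate
#' EQA panel whose target equals the scenario's true mean.
#'
#' @param labs Laboratory identifiers.
#' @param goals TEa goal table; defaults to the builtin urinary goals.
#' @param n_iqc_values IQC series length per scenario (default 360).
#' @param n_eqa_replicates EQA replicates per scenario (default 5).
#' @return Tibble with one row per scenario: `lab`, `analyte`, `level`,
#'   `true_mean`, `eqa_target`, `true_cv`, `true_bias` (signed), `tea`,
#'   `true_sigma`, `n_iqc_values`, `n_eqa_replicates`.
#' @export
default_scenario_grid <- function(labs = paste("Lab", LETTERS[1:5]),
                                  goals = load_tea_goals(),
                                  n_iqc_values = 360,
                                  n_eqa_replicates = 5) {
  grid <- tidyr::expand_grid(
    lab = labs,
    analyte = goals$analyte,
    level = c("level1", "level2")
  ) |>
    dplyr::left_join(ANALYTE_LEVEL_MEANS, by = c("analyte", "level")) |>
    dplyr::mutate(true_mean = dplyr::coalesce(.data$true_mean, 10))
  n <- nrow(grid)
  # Deterministic design: target sigma sweeps the observed range; the
  # bias/CV ratio cycles so imprecision- and trueness-limited assays both
  # occur. CV follows from tea = cv * (sigma + ratio).
  grid |>
    dplyr::mutate(
      tea = tea_for(goals, .data$analyte),
      true_sigma = seq(4, 18, length.out = n),
      bias_ratio = rep_len(c(0.5, 1, 2, 3), n),
      true_cv = .data$tea / (.data$true_sigma + .data$bias_ratio),
      true_bias = .data$bias_ratio * .data$true_cv *
        rep_len(c(1, -1), n),  # alternate bias sign
      eqa_target = .data$true_mean,
      n_iqc_values = n_iqc_values,
      n_eqa_replicates = n_eqa_replicates
    ) |>
    dplyr::select(-"bias_ratio")
}

# Stable per-scenario seed: master seed plus a 28-bit hash of the key, so
# adding or removing scenarios never perturbs the others' streams.
scenario_seed <- function(master_seed, lab, analyte, level, stream = "iqc") {
  key <- paste(lab, analyte, level, stream, sep = "|")
  h <- strtoi(substr(digest::digest(key, algo = "sha1"), 1, 7), base = 16L)
  s <- (as.numeric(master_seed) %% 1000003) * 2017 + h
  as.integer(s %% 2147483647)
}

#' Simulate an internal QC series
#'
#' Values are i.i.d. Gaussian around the biased true mean
#' `true_mean * (1 + true_bias/100)` with SD `true_cv/100` times that
#' mean: the minimal constant-CV noise model behind mean/SD/CV-based IQC
#' statistics. Bias shifts IQC and EQA alike, emulating a single
#' analytical state. Output is byte-deterministic for a fixed seed.
#'
#' @param scenario One scenario row (list or one-row tibble) with fields
#'   `lab`, `analyte`, `level`, `true_mean`, `true_cv`, `true_bias`,
#'   `n_iqc_values`.
#' @param seed Master integer seed.
#' @return Long tibble: `lab`, `analyte`, `level`, `run` (1..n), `value`.
#' @export
simulate_iqc <- function(scenario, seed = 1L) {
  s <- as.list(scenario)
  stopifnot(s$true_cv > 0, s$n_iqc_values >= 2)
  shifted <- s$true_mean * (1 + s$true_bias / 100)
  withr_seed(scenario_seed(seed, s$lab, s$analyte, s$level, "iqc"), {
    v <- stats::rnorm(s$n_iqc_values, mean = shifted,
                      sd = s$true_cv / 100 * shifted)
  })
  tibble::tibble(lab = s$lab, analyte = s$analyte, level = s$level,
                 run = seq_len(s$n_iqc_values), value = v)
}

#' Simulate an EQA replicate panel
#'
#' Replicates are Gaussian around `eqa_target * (1 + true_bias/100)` with
#' the analytical CV; the recorded peer-group target is `eqa_target`
#' itself, so the expected recovered bias equals `true_bias`.
#'
#' @inheritParams simulate_iqc
#' @return Long tibble: `lab`, `analyte`, `level`, `replicate`, `value`,
#'   `target`.
#' @export
simulate_eqa <- function(scenario, seed = 1L) {
  s <- as.list(scenario)
  stopifnot(s$true_cv > 0, s$n_eqa_replicates >= 2)
  shifted <- s$eqa_target * (1 + s$true_bias / 100)
  withr_seed(scenario_seed(seed, s$lab, s$analyte, s$level, "eqa"), {
    v <- stats::rnorm(s$n_eqa_replicates, mean = shifted,
                      sd = s$true_cv / 100 * shifted)
  })
  tibble::tibble(lab = s$lab, analyte = s$analyte, level = s$level,
                 replicate = seq_len(s$n_eqa_replicates), value = v,
                 target = s$eqa_target)
}

# Run code under a local RNG seed without disturbing the caller's stream.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Write a complete synthetic study fixture
#'
#' Simulates every scenario of a grid and writes pipeline-ready
#' `iqc.csv` and `eqa.csv` plus `truth.csv`, the ground-truth table with
#' `true_sigma = (tea - |true_bias|) / true_cv` used by recovery tests.
#' The build is byte-identical for a fixed master seed.
#'
#' @param grid Scenario grid, e.g. [default_scenario_grid()]. Keys
#'   `(lab, analyte, level)` must be unique.
#' @param seed Master integer seed.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
build_study_fixture <- function(grid = default_scenario_grid(), seed = 1L,
                                dir = ".") {
  key <- paste(grid$lab, grid$analyte, grid$level)
  if (anyDuplicated(key)) {
    stop("duplicate scenario key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- seq_len(nrow(grid))
  iqc <- dplyr::bind_rows(lapply(rows, \(i) simulate_iqc(grid[i, ], seed)))
  eqa <- dplyr::bind_rows(lapply(rows, \(i) simulate_eqa(grid[i, ], seed)))
  truth <- grid |>
    dplyr::mutate(true_sigma = (.data$tea - abs(.data$true_bias)) /
                    .data$true_cv)
  paths <- c(iqc = file.path(dir, "iqc.csv"),
             eqa = file.path(dir, "eqa.csv"),
             truth = file.path(dir, "truth.csv"))
  readr::write_csv(iqc, paths[["iqc"]])
  readr::write_csv(eqa, paths[["eqa"]])
  readr::write_csv(truth, paths[["truth"]])
  invisible(paths)
}
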