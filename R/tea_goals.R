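#' Total allowable error (TEa) quality goals
#'
#' Loads the TEa goal table mapping each analyte to its total allowable
#' error, expressed as a percent of the target concentration. The builtin
#' tag `"china_eqa_2020"` returns the state-of-the-art goals derived from
#' the national EQA program of China for the ten routine urinary
#' biochemical analytes (set so that more than 80% of participating
#' laboratories pass proficiency testing).
#'
#' @param source Either the builtin tag `"china_eqa_2020"` or a path to a
#'   JSON file mapping analyte codes to TEa percents, e.g. `{"K": 29}`.
#' @return A tibble of class `tea_goals` with columns `analyte`,
#'   `display_name`, `tea` (percent).
#' @examples
#' goals <- load_tea_goals("china_eqa_2020")
#' tea_for(goals, "Crea")
#' @export
load_tea_goals <- function(source = "china_eqa_2020") {
  if (identical(source, "china_eqa_2020")) {
    tbl <- builtin_tea_china_2020()
  } else {
    if (!file.exists(source)) {
      stop("TEa goal file not found: ", source, call. = FALSE)
    }
    raw <- jsonlite::read_json(source, simplifyVector = TRUE)
    if (!length(raw) || is.null(names(raw))) {
      stop("TEa goal file must be a JSON object mapping analyte to percent",
           call. = FALSE)
    }
    tbl <- tibble::tibble(
      analyte = names(raw),
      display_name = analyte_display_name(names(raw)),
      tea = as.numeric(unlist(raw))
    )
  }
  validate_tea_goals(tbl)
  class(tbl) <- c("tea_goals", class(tbl))
  tbl
}

# Ten urinary biochemical analytes with national-EQA-derived TEa (%).
builtin_tea_china_2020 <- function() {
  tibble::tibble(
    analyte = c("K", "Na", "Cl", "Ca", "P", "GLU", "Urea", "Crea", "TP", "mALB"),
    display_name = analyte_display_name(
      c("K", "Na", "Cl", "Ca", "P", "GLU", "Urea", "Crea", "TP", "mALB")),
    tea = c(29, 26, 26, 31, 23, 20, 21, 17, 44, 30)
  )
}

analyte_display_name <- function(analyte) {
  known <- c(
    K = "potassium", Na = "sodium", Cl = "chloride", Ca = "calcium",
    P = "phosphorus", GLU = "glucose", Urea = "urea", Crea = "creatinine",
    TP = "total protein", mALB = "microalbumin"
  )
  out <- unname(known[analyte])
  out[is.na(out)] <- analyte[is.na(out)]
  out
}

validate_tea_goals <- function(tbl) {
  if (anyDuplicated(tbl$analyte)) {
    stop("duplicate analyte in TEa goal table: ",
         paste(unique(tbl$analyte[duplicated(tbl$analyte)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !is.finite(tbl$tea) | tbl$tea <= 0 | tbl$tea > 100
  if (any(bad)) {
    stop("TEa must be in (0, 100] percent; offending analyte(s): ",
         paste(tbl$analyte[bad], collapse = ", "), call. = FALSE)
  }
  invisible(tbl)
}

#' Look up the TEa goal for one analyte
#'
#' @param goals A `tea_goals` table from [load_tea_goals()].
#' @param analyte Analyte code, e.g. `"Crea"`.
#' @return TEa as a percent (numeric scalar).
#' @export
tea_for <- function(goals, analyte) {
  i <- match(analyte, goals$analyte)
  if (anyNA(i)) {
    stop("no TEa goal defined for analyte: ",
         paste(analyte[is.na(i)], collapse = ", "), call. = FALSE)
  }
  goals$tea[i]
}
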