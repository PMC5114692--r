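# Column mapping between the internal tidy event table and the
# NONMEM-dialect CSV on disk.
nm_cols <- c(ID = "id", TIME = "time_h", AMT = "amt_ug", DV = "dv_ng_per_ml",
             EVID = "evid", MDV = "mdv", BQL = "bql", MISSTIME = "missing_time",
             MISSDOSE = "missing_dose_info", STUDY = "study", VISIT = "visit",
             AGE = "age_years", SEX = "sex", WT = "weight_kg",
             HT = "height_cm", SCR = "scr_umol_l", PMA = "pma_weeks",
             CRCL = "crcl_ml_min")

#' Write / read a PK event dataset as NONMEM-dialect CSV
#'
#' Serialises the event table with conventional column names (`ID`, `TIME`,
#' `AMT`, `DV`, `EVID`, `MDV`, ...) plus covariate and exclusion-flag
#' columns. Missing numeric fields (e.g. `DV` on dose rows) are written as
#' `"."`. A write-then-read round trip reproduces all records, flags and
#' covariates.
#'
#' @param dataset A `pk_dataset` tibble (from [simulate_trial()] or
#'   [read_pk_dataset()]).
#' @param path File path.
#' @return `write_pk_dataset()` returns `path` invisibly;
#'   `read_pk_dataset()` returns a validated `pk_dataset` tibble.
#' @export
write_pk_dataset <- function(dataset, path) {
  out <- dataset[, unname(nm_cols)]
  names(out) <- names(nm_cols)
  out$BQL <- as.integer(out$BQL)
  out$MISSTIME <- as.integer(out$MISSTIME)
  out$MISSDOSE <- as.integer(out$MISSDOSE)
  readr::write_csv(out, path, na = ".")
  invisible(path)
}

#' @rdname write_pk_dataset
#' @export
read_pk_dataset <- function(path) {
  # parse issues are re-surfaced below via problems()/column checks
  raw <- suppressWarnings(
    readr::read_csv(path, na = ".", show_col_types = FALSE,
                    col_types = readr::cols(
                           ID = "i", TIME = "d", AMT = "d", DV = "d",
                           EVID = "i", MDV = "i", BQL = "i", MISSTIME = "i",
                           MISSDOSE = "i", STUDY = "c", VISIT = "c",
                           AGE = "d", SEX = "c", WT = "d", HT = "d",
                           SCR = "d", PMA = "d", CRCL = "d")))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("unparseable rows at lines: ",
         paste(unique(probs$row), collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(names(nm_cols), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ds <- raw[, names(nm_cols)]
  names(ds) <- unname(nm_cols)
  ds$bql <- ds$bql == 1L
  ds$missing_time <- ds$missing_time == 1L
  ds$missing_dose_info <- ds$missing_dose_info == 1L
  bad <- ds |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(mono = !is.unsorted(.data$time_h)) |>
    dplyr::filter(!.data$mono)
  if (nrow(bad) > 0) {
    stop("non-monotone times within subject(s): ",
         paste(bad$id, collapse = ", "), call. = FALSE)
  }
  class(ds) <- c("pk_dataset", class(ds))
  ds
}

#' Export a concentration profile as tidy CSV
#'
#' @param profile A `pk_profile` tibble.
#' @param path File path.
#' @param subject Optional subject identifier column value.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, subject = NA) {
  readr::write_csv(tibble::tibble(subject = subject,
                                  time_h = profile$time_h,
                                  conc_ng_per_ml = profile$conc_ng_per_ml),
                   path)
  invisible(path)
}
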