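#' Apply record-exclusion rules to a PK dataset
#'
#' Removes observation records that are below the assay's lower limit of
#' quantification (the flagged `bql` records plus any observation with
#' `DV < lloq`), records with missing sampling time, and records with
#' missing dosing information. Subjects left with zero observations have
#' all their rows dropped and leave the subject count. Dose records are
#' never excluded (except with a fully dropped subject). BQL handling is
#' exclusion (the "M1" approach); retained concentration values are never
#' modified, and the filter is idempotent and order-preserving.
#'
#' @param dataset A `pk_dataset` tibble.
#' @param lloq Optional numeric LLOQ (ng/mL) applied on top of the `bql`
#'   flag; `NULL` uses only the flag.
#' @return A list of class `pk_prepared` with elements `data` (the filtered
#'   `pk_dataset`) and `report` (an `exclusion_report` one-row tibble with
#'   counts of input, excluded-by-reason, retained records and retained
#'   subjects). Counts refer to observation records.
#' @examples
#' d <- design_rich(n_subjects = 4)
#' ds <- simulate_trial(generate_cohort(d, seed = 1), d,
#'                      population_model(), seed = 2)
#' prep <- filter_records(ds)
#' prep$report
#' @export
filter_records <- function(dataset, lloq = NULL) {
  obs <- dataset$evid == 0L
  is_bql <- obs & (dataset$bql |
                     (!is.null(lloq) & !is.na(dataset$dv_ng_per_ml) &
                        dataset$dv_ng_per_ml < (lloq %||% -Inf)))
  is_misst <- obs & dataset$missing_time & !is_bql
  is_missd <- obs & dataset$missing_dose_info & !is_bql & !is_misst
  is_other <- obs & is.na(dataset$dv_ng_per_ml) &
    !is_bql & !is_misst & !is_missd
  drop <- is_bql | is_misst | is_missd | is_other

  kept <- dataset[!drop, ]
  keep_ids <- unique(kept$id[kept$evid == 0L])
  kept <- kept[kept$id %in% keep_ids, ]

  report <- tibble::tibble(
    n_input_records = sum(obs),
    n_excluded_bql = sum(is_bql),
    n_excluded_missing_time = sum(is_misst),
    n_excluded_missing_dose_info = sum(is_missd),
    n_excluded_other = sum(is_other),
    n_retained = sum(kept$evid == 0L),
    n_subjects_retained = length(keep_ids)
  )
  class(report) <- c("exclusion_report", class(report))
  structure(list(data = kept, report = report), class = "pk_prepared")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.pk_prepared <- function(x, ...) {
  r <- x$report
  cat("<pk_prepared> ", r$n_retained, " of ", r$n_input_records,
      " observation records retained from ", r$n_subjects_retained,
      " subjects\n", sep = "")
  cat("  excluded: ", r$n_excluded_bql, " BQL, ",
      r$n_excluded_missing_time, " missing time, ",
      r$n_excluded_missing_dose_info, " missing dose info, ",
      r$n_excluded_other, " other\n", sep = "")
  invisible(x)
}

#' Extract the exclusion report from a prepared dataset
#' @param x A `pk_prepared` object.
#' @return The `exclusion_report` tibble.
#' @export
exclusion_report <- function(x) {
  stopifnot(inherits(x, "pk_prepared"))
  x$report
}
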