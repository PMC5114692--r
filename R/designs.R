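#' Trial designs for the two pediatric studies
#'
#' `design_rich()` describes a phase-1-style single-dose study: children
#' aged 4-12 years receive one oral dose of 0.03 mg/kg solution and are
#' sampled at 13 scheduled times over 72 h (assay LLOQ 0.1 ng/mL).
#'
#' `design_sparse()` describes a phase-3-style sparse-sampling study:
#' children aged 1.7-18 years receive 0.04 mg/kg once daily (capped at
#' 2 mg); after 4 weeks a fraction of subjects is up-titrated to
#' 0.06 mg/kg (insufficient response) and a smaller fraction down-titrated
#' to 0.02 mg/kg (tolerability), re-capped at 2 mg. One sample is drawn
#' 1-3 h after the first dose and two trough samples 14-26 h post-dose at
#' weeks 8 and 24 (LLOQ 0.2 ng/mL).
#'
#' @param n_subjects Number of subjects to simulate.
#' @param uptitrate_frac,downtitrate_frac For the sparse design, fractions
#'   of subjects moved to 0.06 and 0.02 mg/kg at the week-4 adjustment.
#' @return An object of class `pk_design` (a named list).
#' @examples
#' design_rich()
#' design_sparse(n_subjects = 50)
#' @export
design_rich <- function(n_subjects = 38) {
  structure(list(
    label = "rich",
    schedule = "single",
    n_subjects = as.integer(n_subjects),
    dose_mg_per_kg = 0.03,
    cap_mg = 2,
    sample_times = c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 18, 24, 48, 72),
    lloq = 0.1,
    sigma_log = 0.14,
    age_range = c(4, 12),
    age_median = 8.5,
    age_sdlog = 0.35,
    weight_range = c(15, 61),
    frac_female = 0.342
  ), class = "pk_design")
}

#' @rdname design_rich
#' @export
design_sparse <- function(n_subjects = 107, uptitrate_frac = 0.3,
                          downtitrate_frac = 0.05) {
  stopifnot(uptitrate_frac + downtitrate_frac <= 1)
  structure(list(
    label = "sparse",
    schedule = "once_daily",
    n_subjects = as.integer(n_subjects),
    dose_mg_per_kg = 0.04,
    cap_mg = 2,
    day1_window = c(1, 3),
    trough_weeks = c(8, 24),
    trough_window = c(14, 26),
    adjust_week = 4,
    duration_weeks = 24,
    uptitrate_frac = uptitrate_frac,
    uptitrate_dose = 0.06,
    downtitrate_frac = downtitrate_frac,
    downtitrate_dose = 0.02,
    lloq = 0.2,
    sigma_log = 0.35,
    age_range = c(1.7, 18),
    age_median = 7.9,
    age_sdlog = 0.55,
    weight_range = c(11, 110),
    frac_female = 0.577
  ), class = "pk_design")
}

#' @export
print.pk_design <- function(x, ...) {
  cat("<pk_design>", x$label, "|", x$schedule, "|", x$n_subjects,
      "subjects |", x$dose_mg_per_kg, "mg/kg (cap", x$cap_mg,
      "mg) | LLOQ", x$lloq, "ng/mL\n")
  invisible(x)
}
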