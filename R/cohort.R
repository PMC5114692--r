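# Simple pediatric growth reference: median weight (kg) and height (cm)
# by age, linearly interpolated. Generator convenience values, not claims
# about any trial population.
growth_age <- c(0.5, 1, 1.5, 2, 3, 4, 5, 6, 7, 8, 9, 10,
                11, 12, 13, 14, 15, 16, 17, 18)
growth_wt <- c(7.5, 9.5, 11, 12.3, 14.5, 16.5, 18.5, 21, 23.5, 26.5,
               29.5, 33, 37, 41, 46, 50.5, 54.5, 58, 60.5, 62)
growth_ht <- c(67, 75, 81, 87, 95, 102, 109, 115, 121, 128,
               133, 138, 144, 150, 157, 163, 167, 170, 172, 173)

#' Median body weight and height for age
#'
#' Piecewise-linear pediatric growth medians (sexes pooled) used by the
#' cohort generator and by the age-by-dose exposure grid.
#'
#' @param age_years Age in years; clamped to the 0.5-18 year table range.
#' @return `median_weight_for_age()`: weight in kg;
#'   `median_height_for_age()`: height in cm.
#' @export
median_weight_for_age <- function(age_years) {
  approx(growth_age, growth_wt, xout = age_years, rule = 2)$y
}

#' @rdname median_weight_for_age
#' @export
median_height_for_age <- function(age_years) {
  approx(growth_age, growth_ht, xout = age_years, rule = 2)$y
}

# lognormal age truncated to a range by resampling
sample_ages <- function(n, median_age, sdlog, range, max_iter = 200) {
  out <- numeric(0)
  it <- 0
  while (length(out) < n && it < max_iter) {
    draw <- exp(rnorm(2 * n, log(median_age), sdlog))
    out <- c(out, draw[draw >= range[1] & draw <= range[2]])
    it <- it + 1
  }
  out[seq_len(n)]
}

capped_dose_mg <- function(mg_per_kg, weight_kg, cap_mg) {
  pmin(mg_per_kg * weight_kg, cap_mg)
}

#' Generate a virtual cohort for a trial design
#'
#' Draws ages from a truncated lognormal targeting the study's median age
#' and range, body weights from the growth median for age with lognormal
#' scatter (SD 0.18 on the log scale, clamped to the study's observed
#' weight envelope), heights from the growth median adjusted for relative
#' weight, and serum creatinine linear in age with mild lognormal scatter.
#' Doses are assigned per kg with the 2 mg cap; for the sparse design the
#' week-4 adjustment moves a configurable fraction of subjects to
#' 0.06 mg/kg and a smaller fraction to 0.02 mg/kg (re-capped).
#'
#' @param design A [design_rich()] or [design_sparse()] object.
#' @param n Number of subjects (defaults to the design's `n_subjects`).
#' @param seed Integer seed; the same seed yields an identical cohort.
#' @return A tibble with one row per subject: identifiers, covariates
#'   (including derived `pma_weeks` and `crcl_ml_min`) and assigned doses
#'   (`dose_mg`, and for the sparse design `dose_mg_adj` after week 4).
#' @examples
#' cohort <- generate_cohort(design_rich(), seed = 1)
#' @export
generate_cohort <- function(design, n = design$n_subjects, seed = 1) {
  stopifnot(inherits(design, "pk_design"))
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  n <- as.integer(n)
  set.seed(seed)
  if (n == 0L) {
    return(tibble::tibble(id = integer(), study = character(),
                          age_years = numeric(), sex = character(),
                          weight_kg = numeric(), height_cm = numeric(),
                          scr_umol_l = numeric(), pma_weeks = numeric(),
                          crcl_ml_min = numeric(), dose_mg = numeric(),
                          dose_mg_adj = numeric()))
  }
  age <- sample_ages(n, design$age_median, design$age_sdlog,
                     design$age_range)
  z <- pmax(pmin(rnorm(n), 2.5), -2.5)
  wt <- median_weight_for_age(age) * exp(0.18 * z)
  wt <- pmax(pmin(wt, design$weight_range[2]), design$weight_range[1])
  ht <- median_height_for_age(age) *
    (wt / median_weight_for_age(age))^0.3
  scr <- (22 + 1.9 * age) * exp(rnorm(n, 0, 0.12))
  sex <- ifelse(runif(n) < design$frac_female, "F", "M")
  dose_mg <- capped_dose_mg(design$dose_mg_per_kg, wt, design$cap_mg)
  dose_mg_adj <- dose_mg
  if (identical(design$schedule, "once_daily")) {
    u <- runif(n)
    mgkg_adj <- rep(design$dose_mg_per_kg, n)
    mgkg_adj[u < design$uptitrate_frac] <- design$uptitrate_dose
    mgkg_adj[u >= design$uptitrate_frac &
               u < design$uptitrate_frac + design$downtitrate_frac] <-
      design$downtitrate_dose
    dose_mg_adj <- capped_dose_mg(mgkg_adj, wt, design$cap_mg)
  }
  tibble::tibble(id = seq_len(n), study = design$label,
                 age_years = age, sex = sex, weight_kg = wt,
                 height_cm = ht, scr_umol_l = scr) |>
    derive_covariates() |>
    dplyr::mutate(dose_mg = dose_mg, dose_mg_adj = dose_mg_adj)
}
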