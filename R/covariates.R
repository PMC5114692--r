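#' Postmenstrual age from postnatal age
#'
#' Postmenstrual age is the calculated postnatal age in weeks plus 40 weeks
#' of gestation (term gestation is assumed for all subjects). Years are
#' converted at 365.25/7 weeks per year.
#'
#' @param age_years Postnatal age in years (>= 0); vectorised.
#' @return Postmenstrual age in weeks.
#' @examples
#' compute_pma(2) # 144.36 weeks
#' @export
compute_pma <- function(age_years) {
  if (any(age_years < 0)) stop("age must be >= 0", call. = FALSE)
  age_years * 365.25 / 7 + 40
}

#' Creatinine clearance from height, serum creatinine and weight
#'
#' Pediatric creatinine clearance (mL/min) computed as
#' `42.5 * height / serum_creatinine * (weight / 70)^0.7`, i.e. a
#' height-over-creatinine rule with a body-weight adjustment.
#'
#' @param height_cm Height (cm).
#' @param scr_umol_l Serum creatinine (umol/L).
#' @param weight_kg Body weight (kg).
#' @return Creatinine clearance (mL/min); vectorised.
#' @examples
#' compute_crcl(130, 40, 27.9) # about 72.5 mL/min
#' @export
compute_crcl <- function(height_cm, scr_umol_l, weight_kg) {
  if (any(height_cm <= 0) || any(scr_umol_l <= 0) || any(weight_kg <= 0)) {
    stop("height, serum creatinine and weight must be > 0", call. = FALSE)
  }
  42.5 * height_cm / scr_umol_l * (weight_kg / 70)^0.7
}

# PMA (weeks) of a child exactly 24 months old; above this renal function
# is treated as fully mature.
pma_24_months <- function() 24 * 365.25 / 12 / 7 + 40

#' Renal maturation fraction
#'
#' Sigmoidal (Hill) fraction of mature glomerular filtration as a function
#' of postmenstrual age: `PMA^3.4 / (47.7^3.4 + PMA^3.4)`, with
#' half-maturation at 47.7 weeks. Renal function is assumed fully mature
#' (fraction 1) for children older than 24 months of postnatal age; the
#' unclamped fraction at that boundary already exceeds 0.975, so the step
#' introduced by the clamp is below 2.5%.
#'
#' @param pma_weeks Postmenstrual age (weeks), > 0; vectorised.
#' @return Maturation fraction in (0, 1].
#' @examples
#' maturation_gfr(47.7) # 0.5 at the Hill midpoint
#' @export
maturation_gfr <- function(pma_weeks) {
  if (any(pma_weeks <= 0)) stop("pma_weeks must be > 0", call. = FALSE)
  frac <- pma_weeks^3.4 / (47.7^3.4 + pma_weeks^3.4)
  ifelse(pma_weeks > pma_24_months(), 1, frac)
}

#' Derive computed covariates for a covariate table
#'
#' Adds `pma_weeks` (from age) and `crcl_ml_min` (from height, serum
#' creatinine and weight) to a covariate data frame. Both are always
#' recomputed, never trusted from the input.
#'
#' @param cov Data frame with columns `age_years`, `weight_kg`, `height_cm`,
#'   `scr_umol_l`.
#' @return The input as a tibble with `pma_weeks` and `crcl_ml_min`
#'   (re)computed.
#' @export
derive_covariates <- function(cov) {
  cov |>
    tibble::as_tibble() |>
    dplyr::mutate(
      pma_weeks = compute_pma(.data$age_years),
      crcl_ml_min = compute_crcl(.data$height_cm, .data$scr_umol_l,
                                 .data$weight_kg)
    )
}

#' Impute missing covariates from study medians
#'
#' Fills missing `weight_kg`, `height_cm` and `scr_umol_l` with the
#' median of the non-missing values within the same study (deterministic
#' median imputation). Age must be observed: postmenstrual age is always
#' derived from it, never imputed. Derived covariates are recomputed
#' afterwards.
#'
#' @param cov Covariate data frame with a `study` column.
#' @return The completed covariate tibble with `pma_weeks` and
#'   `crcl_ml_min` recomputed.
#' @export
impute_covariates <- function(cov) {
  if (any(is.na(cov$age_years))) {
    stop("age_years must be observed for all subjects", call. = FALSE)
  }
  fill_median <- function(x) {
    x[is.na(x)] <- median(x, na.rm = TRUE)
    x
  }
  cov |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$study) |>
    dplyr::mutate(dplyr::across(c("weight_kg", "height_cm", "scr_umol_l"),
                                fill_median)) |>
    dplyr::ungroup() |>
    derive_covariates()
}

#' Individual PK parameters from covariates and random effects
#'
#' Maps a population model plus patient covariates and log-scale random
#' effects to individual structural parameters: clearances scale with
#' `(weight/70)^0.75`, volumes with `(weight/70)^1`, and the renal
#' maturation fraction multiplies elimination clearance only. Absorption
#' parameters and bioavailability are not scaled. Random effects act
#' multiplicatively as `exp(eta)`.
#'
#' @param pop A [population_model()].
#' @param cov One row of covariates (list or data frame row) with
#'   `age_years` and `weight_kg`.
#' @param eta Named list/vector of random effects (`cl`, `v2`, `v3`, and
#'   optionally `ka1`, `ka2`); missing entries default to 0.
#' @param study Study label selecting the typical clearance, one of
#'   `pop$studies`.
#' @return A [pk_params()] object.
#' @examples
#' pop <- population_model()
#' individual_parameters(pop, list(age_years = 8, weight_kg = 24),
#'                       study = "sparse")
#' @export
individual_parameters <- function(pop, cov, eta = list(), study) {
  stopifnot(inherits(pop, "pop_model"))
  if (!study %in% pop$studies) {
    stop("unknown study label: ", study, call. = FALSE)
  }
  get_eta <- function(nm) {
    v <- eta[[nm]]
    if (is.null(v)) 0 else v
  }
  wt <- cov$weight_kg
  mat <- maturation_gfr(compute_pma(cov$age_years))
  f_cl <- (wt / 70)^0.75
  f_v <- wt / 70
  pk_params(
    cl = pop$cl_tv[[study]] * f_cl * mat * exp(get_eta("cl")),
    v2 = pop$v2_tv * f_v * exp(get_eta("v2")),
    q = pop$q_tv * f_cl,
    v3 = pop$v3_tv * f_v * exp(get_eta("v3")),
    ka1 = pop$ka1 * exp(get_eta("ka1")),
    ka2 = pop$ka2 * exp(get_eta("ka2")),
    mtime = pop$mtime,
    f1 = pop$f1
  )
}
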