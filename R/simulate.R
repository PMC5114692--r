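#' Simulate a PK trial for a virtual cohort
#'
#' Draws per-subject random effects from the population model's log-scale
#' IIV SDs, computes individual concentration-time courses with the
#' structural model, and applies multiplicative residual noise
#' (`DV = prediction * exp(eps)`, `eps ~ N(0, sigma_study^2)` - i.e. an
#' additive error on log concentrations). Observations below the design's
#' LLOQ are flagged `bql` (the censored numeric value is preserved).
#'
#' For the rich design each subject receives one dose at time 0 and is
#' sampled at the 13 scheduled times. For the sparse design subjects are
#' dosed once daily for 24 weeks (amount switching at the week-4
#' adjustment); the day-1 sample is drawn uniformly in the 1-3 h window and
#' the week-8/24 trough samples uniformly 14-26 h after the preceding dose.
#' The daily dose immediately following each trough visit is skipped
#' (clinic visit before that day's dose), so a trough drawn beyond 24 h is
#' not contaminated by a fresh absorption phase.
#'
#' Exclusion artifacts: `n_missing_time` and `n_missing_dose` observation
#' records are flagged as missing sampling time / missing dosing
#' information; with `force_excluded_subject = TRUE` (sparse design) one
#' seed-stable subject additionally has all its observations flagged, so
#' the prepared dataset loses that subject entirely.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param design The matching [design_rich()]/[design_sparse()] object.
#' @param pop A [population_model()].
#' @param seed Integer seed.
#' @param n_missing_time,n_missing_dose Number of observation records to
#'   flag with exclusion artifacts.
#' @param force_excluded_subject For the sparse design, force one subject's
#'   records to all be excluded.
#'
#' @return A `pk_dataset` tibble of ordered event records (`evid` 1 = dose,
#'   0 = observation) with dosing amounts in ug, observed concentrations in
#'   ng/mL, exclusion flags and subject covariates. The simulated random
#'   effects are attached as attribute `"eta"`.
#' @examples
#' d <- design_rich(n_subjects = 4)
#' ds <- simulate_trial(generate_cohort(d, seed = 1), d,
#'                      population_model(), seed = 2)
#' @export
simulate_trial <- function(cohort, design, pop, seed = 1,
                           n_missing_time = 0, n_missing_dose = 0,
                           force_excluded_subject =
                             identical(design$schedule, "once_daily")) {
  stopifnot(inherits(design, "pk_design"), inherits(pop, "pop_model"))
  if (!design$label %in% pop$studies) {
    stop("population model has no study labelled ", design$label,
         call. = FALSE)
  }
  if (nrow(cohort) > 0 && !all(cohort$study == design$label)) {
    stop("cohort and design labels disagree", call. = FALSE)
  }
  set.seed(seed)
  study <- design$label
  sig <- pop$sigma[[study]]
  if (sig < 0) stop("sigma must be >= 0", call. = FALSE)

  n <- nrow(cohort)
  eta_tbl <- tibble::tibble(
    id = cohort$id,
    eta_cl = rnorm(n, 0, pop$omega$cl[[study]]),
    eta_v2 = rnorm(n, 0, pop$omega$v2),
    eta_v3 = rnorm(n, 0, pop$omega$v3),
    eta_ka1 = rnorm(n, 0, pop$omega$ka1),
    eta_ka2 = rnorm(n, 0, pop$omega$ka2)
  )

  subj_events <- function(i) {
    sub <- cohort[i, ]
    if (identical(design$schedule, "single")) {
      doses <- tibble::tibble(time = 0, amount = sub$dose_mg * 1000)
      obs_t <- design$sample_times
      visit <- sprintf("%gh", obs_t)
    } else {
      days <- 0:(design$duration_weeks * 7)
      # skip the dose on the day after each trough visit
      skip <- design$trough_weeks * 7 + 1
      days <- setdiff(days, skip)
      amt <- ifelse(days < design$adjust_week * 7,
                    sub$dose_mg, sub$dose_mg_adj) * 1000
      doses <- tibble::tibble(time = days * 24, amount = amt)
      t_day1 <- runif(1, design$day1_window[1], design$day1_window[2])
      t_troughs <- design$trough_weeks * 7 * 24 +
        runif(length(design$trough_weeks), design$trough_window[1],
              design$trough_window[2])
      obs_t <- c(t_day1, t_troughs)
      visit <- c("day1", sprintf("week%d", design$trough_weeks))
    }
    eta_i <- as.list(eta_tbl[i, c("eta_cl", "eta_v2", "eta_v3",
                                  "eta_ka1", "eta_ka2")])
    names(eta_i) <- c("cl", "v2", "v3", "ka1", "ka2")
    params <- individual_parameters(pop, sub, eta_i, study)
    pred <- solve_regimen(params, doses, obs_t)$conc_ng_per_ml
    if (any(!is.finite(pred))) {
      stop("non-finite prediction for subject ", sub$id, call. = FALSE)
    }
    dv <- pred * exp(rnorm(length(pred), 0, sig))
    dose_rows <- tibble::tibble(
      id = sub$id, time_h = doses$time, evid = 1L, amt_ug = doses$amount,
      dv_ng_per_ml = NA_real_, mdv = 1L, bql = FALSE, visit = NA_character_)
    obs_rows <- tibble::tibble(
      id = sub$id, time_h = obs_t, evid = 0L, amt_ug = NA_real_,
      dv_ng_per_ml = dv, mdv = 0L, bql = dv < design$lloq, visit = visit)
    dplyr::arrange(dplyr::bind_rows(dose_rows, obs_rows),
                   .data$time_h, dplyr::desc(.data$evid))
  }

  events <- purrr::map_dfr(seq_len(n), subj_events)
  events$missing_time <- FALSE
  events$missing_dose_info <- FALSE

  obs_idx <- which(events$evid == 0L)
  if (n_missing_time > 0 && length(obs_idx) > 0) {
    pick <- sample(obs_idx, min(n_missing_time, length(obs_idx)))
    events$missing_time[pick] <- TRUE
    obs_idx <- setdiff(obs_idx, pick)
  }
  if (n_missing_dose > 0 && length(obs_idx) > 0) {
    pick <- sample(obs_idx, min(n_missing_dose, length(obs_idx)))
    events$missing_dose_info[pick] <- TRUE
  }
  if (force_excluded_subject && identical(design$schedule, "once_daily") &&
      n > 0) {
    drop_id <- cohort$id[sample.int(n, 1)]
    sel <- events$id == drop_id & events$evid == 0L
    events$missing_dose_info[sel] <- TRUE
  }

  out <- events |>
    dplyr::left_join(
      dplyr::select(cohort, "id", "study", "age_years", "sex", "weight_kg",
                    "height_cm", "scr_umol_l", "pma_weeks", "crcl_ml_min"),
      by = "id") |>
    dplyr::arrange(.data$id, .data$time_h, dplyr::desc(.data$evid))
  attr(out, "eta") <- eta_tbl
  class(out) <- c("pk_dataset", class(out))
  out
}
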