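# Independent numerical oracles and hand-built fixtures used across tests.

# High-accuracy stiff-ODE solution for a single oral dose with the depot
# rate constant switched at mtime (independent of the package's
# closed-form path).
ode_conc_oracle <- function(params, dose_ug, times, rtol = 1e-10) {
  rhs <- function(t, y, parms) {
    ka <- if (t < params$mtime) params$ka1 else params$ka2
    k10 <- params$cl / params$v2
    k12 <- params$q / params$v2
    k21 <- params$q / params$v3
    list(c(-ka * y[1],
           ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
           k12 * y[2] - k21 * y[3]))
  }
  y0 <- c(d = params$f1 * dose_ug, c = 0, p = 0)
  tt <- sort(unique(c(0, params$mtime, times)))
  out <- deSolve::ode(y0, tt, rhs, NULL, rtol = rtol, atol = 1e-12)
  stats::approx(out[, 1], out[, 3], xout = times)$y / params$v2
}

# -2 log marginal likelihood by adaptive 1-D quadrature for subjects with
# a single random effect on clearance (log-normal observation model).
quad_ofv_oracle <- function(pop, dataset) {
  ids <- unique(dataset$id)
  total <- 0
  for (i in ids) {
    rows <- dataset[dataset$id == i, ]
    obs <- rows[rows$evid == 0L, ]
    dose <- rows[rows$evid == 1L & !is.na(rows$amt_ug), ]
    study <- rows$study[1]
    om <- pop$omega$cl[[study]]
    sig <- pop$sigma[[study]]
    wt <- rows$weight_kg[1]
    mat <- maturation_gfr(compute_pma(rows$age_years[1]))
    lik <- function(eta) {
      vapply(eta, function(e) {
        p <- pk_params(cl = pop$cl_tv[[study]] * (wt / 70)^0.75 * mat *
                         exp(e),
                       v2 = pop$v2_tv * wt / 70, q = pop$q_tv *
                         (wt / 70)^0.75,
                       v3 = pop$v3_tv * wt / 70, ka1 = pop$ka1,
                       ka2 = pop$ka2, mtime = pop$mtime, f1 = pop$f1)
        f <- solve_regimen(p, data.frame(time = dose$time_h,
                                         amount = dose$amt_ug),
                           obs$time_h)$conc_ng_per_ml
        prod(stats::dnorm(log(obs$dv_ng_per_ml), log(f), sig)) *
          stats::dnorm(e, 0, om)
      }, numeric(1))
    }
    marg <- stats::integrate(lik, -8 * om, 8 * om, rel.tol = 1e-10)$value
    total <- total - 2 * log(marg)
  }
  total
}

# Minimal hand-built event dataset (pk_dataset layout) for filter and
# estimation fixtures.
make_dataset <- function(ids, obs_times, dv, dose_time = 0, dose_ug = 1000,
                         study = "rich", weight_kg = 70, age_years = 10,
                         bql = FALSE, missing_time = FALSE,
                         missing_dose_info = FALSE) {
  rows <- purrr::map_dfr(seq_along(ids), function(k) {
    i <- ids[k]
    dplyr::bind_rows(
      tibble::tibble(id = i, time_h = dose_time, evid = 1L,
                     amt_ug = dose_ug, dv_ng_per_ml = NA_real_, mdv = 1L,
                     bql = FALSE, missing_time = FALSE,
                     missing_dose_info = FALSE, visit = NA_character_),
      tibble::tibble(id = i, time_h = obs_times[[k]], evid = 0L,
                     amt_ug = NA_real_, dv_ng_per_ml = dv[[k]], mdv = 0L,
                     bql = rep_len(bql, length(obs_times[[k]])),
                     missing_time = rep_len(missing_time,
                                            length(obs_times[[k]])),
                     missing_dose_info = rep_len(missing_dose_info,
                                                 length(obs_times[[k]])),
                     visit = sprintf("%gh", obs_times[[k]])))
  })
  rows$study <- study
  rows$age_years <- age_years
  rows$sex <- "F"
  rows$weight_kg <- weight_kg
  rows$height_cm <- 140
  rows$scr_umol_l <- 40
  rows$pma_weeks <- compute_pma(age_years)
  rows$crcl_ml_min <- compute_crcl(140, 40, weight_kg)
  class(rows) <- c("pk_dataset", class(rows))
  rows
}

# default typical parameters used in several structural tests
typical_rich_params <- function() {
  pk_params(cl = 22.9, v2 = 446, q = 16.9, v3 = 248)
}

# toy fixture: subjects with a single random effect on clearance
toy_pop <- function(om_cl = 0.3, sig = 0.2) {
  population_model(omega = list(cl = c(rich = om_cl, sparse = om_cl),
                                v2 = 0, v3 = 0),
                   sigma = c(rich = sig, sparse = sig))
}

toy_dataset <- function(etas, sig = 0.2, seed = 1) {
  set.seed(seed)
  pop <- toy_pop(sig = sig)
  times <- c(1, 6, 24)
  purrr::map_dfr(seq_along(etas), function(i) {
    p <- individual_parameters(pop, list(age_years = 9, weight_kg = 30),
                               eta = list(cl = etas[i]), study = "rich")
    f <- solve_regimen(p, data.frame(time = 0, amount = 900),
                       times)$conc_ng_per_ml
    make_dataset(ids = i, obs_times = list(times),
                 dv = list(f * exp(rnorm(3, 0, sig))), dose_ug = 900,
                 weight_kg = 30, age_years = 9)
  })
}


# Fixture mirroring the rich single-dose study bookkeeping: 38 subjects
# with 13 scheduled samples each (494 records), 13 of which are excluded
# as BQL or missing sampling time.
rich_fixture <- function() {
  times <- c(0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 18, 24, 48, 72)
  ds <- make_dataset(ids = 1:38,
                     obs_times = replicate(38, times, simplify = FALSE),
                     dv = replicate(38, rep(2.5, 13), simplify = FALSE))
  obs_idx <- which(ds$evid == 0L)
  ds$bql[obs_idx[c(13, 26, 39, 52, 65, 78, 91, 104, 117)]] <- TRUE
  ds$missing_time[obs_idx[c(130, 143, 156, 169)]] <- TRUE
  ds
}

# Fixture mirroring the sparse multi-dose study bookkeeping: 291 collected
# observations over 107 subjects; 25 BQL, 1 not-analyzed, 21 with missing
# dosing information, arranged so one subject loses every record.
sparse_fixture <- function() {
  # subjects 1..92 contribute 3 observations, 93..107 contribute 1 (291)
  n_obs <- c(rep(3, 92), rep(1, 15))
  obs_times <- purrr::map(n_obs, function(k) c(2, 1350, 4050)[seq_len(k)])
  dv <- purrr::map(n_obs, function(k) rep(1.4, k))
  ds <- make_dataset(ids = 1:107, obs_times = obs_times, dv = dv,
                     study = "sparse")
  obs_idx <- which(ds$evid == 0L)
  stopifnot(length(obs_idx) == 291)
  # subject 1 loses all three records to missing dosing information
  subj1 <- which(ds$evid == 0L & ds$id == 1)
  ds$missing_dose_info[subj1] <- TRUE
  # 18 further missing-dose records, 25 BQL, 1 not analyzed (missing DV),
  # spread one per subject so no other subject loses all its records
  first_obs_of <- function(i) which(ds$evid == 0L & ds$id == i)[1]
  ds$missing_dose_info[vapply(2:19, first_obs_of, integer(1))] <- TRUE
  ds$bql[vapply(20:44, first_obs_of, integer(1))] <- TRUE
  ds$dv_ng_per_ml[first_obs_of(45)] <- NA_real_
  ds
}

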