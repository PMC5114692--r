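#' Residual diagnostics table
#'
#' Computes population and individual predictions and conditional weighted
#' residuals (CWRES) for every retained observation. CWRES follow the FOCE
#' linearisation at the conditional mode: the residual
#' `log DV - log PRED` linearised at `eta_hat`
#' (`y - f(eta_hat) + G eta_hat`) is whitened by the model-implied
#' covariance `G Omega G' + sigma^2 I` (lower-Cholesky whitening per
#' subject). IWRES is `(log DV - log IPRED) / sigma`. Under a correct model
#' CWRES are approximately standard normal. Subjects with a singular
#' covariance are flagged and excluded from the table with a warning.
#'
#' @param fit A `pru_fit` object.
#' @param dataset The dataset that was fitted (used for observation
#'   metadata: times, visits).
#' @return A tibble of class `pru_residuals`: one row per observation with
#'   `pred`, `ipred` (ng/mL), `cwres`, `iwres`, `time_after_dose`.
#' @export
compute_cwres <- function(fit, dataset) {
  stopifnot(inherits(fit, "pru_fit"))
  pop <- fit$pop
  out <- purrr::map2(fit$subjects, fit$details, function(s, d) {
    n <- s$n_obs
    if (n == 0) return(NULL)
    om <- c(pop$omega$cl[[s$study_label]], pop$omega$v2, pop$omega$v3)
    sig <- pop$sigma[[s$study_label]]
    G <- d$G
    C <- G %*% diag(om^2, 3) %*% t(G) + diag(sig^2, n)
    L <- try(t(chol(C)), silent = TRUE)
    if (inherits(L, "try-error")) {
      warning("singular covariance for subject ", s$id,
              "; excluded from residual table", call. = FALSE)
      return(NULL)
    }
    res <- s$y - d$ipred_log + as.numeric(G %*% d$eta)
    cwres <- forwardsolve(L, res)
    iwres <- (s$y - d$ipred_log) / sig
    rows <- dataset[dataset$id == s$id, ]
    dose_t <- rows$time_h[rows$evid == 1L]
    tad <- vapply(s$obs_times, function(t) {
      prior <- dose_t[dose_t <= t]
      if (length(prior) == 0) t else t - max(prior)
    }, numeric(1))
    tibble::tibble(id = s$id, study = s$study_label, time_h = s$obs_times,
                   time_after_dose = tad, dv = exp(s$y),
                   pred = exp(d$pred_log), ipred = exp(d$ipred_log),
                   cwres = cwres, iwres = iwres)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("pru_residuals", class(out))
  out
}

#' Ordered CWRES versus normal scores
#'
#' Quantile-quantile input data: ordered CWRES paired with the
#' corresponding standard-normal quantiles. A pure function of the
#' residual table.
#'
#' @param residuals A `pru_residuals` tibble from [compute_cwres()].
#' @return A tibble with `normal_score` and `cwres_ordered`.
#' @export
cwres_qq <- function(residuals) {
  x <- sort(residuals$cwres)
  n <- length(x)
  tibble::tibble(normal_score = qnorm((seq_len(n) - 0.5) / n),
                 cwres_ordered = x)
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets from the fitted model at the
#' observed design points (same subjects, doses and sampling times),
#' computes concentration percentiles per time bin for each replicate, and
#' summarises the across-replicate distribution of each percentile as a
#' band, alongside the observed percentiles. Bins are the dataset's `visit`
#' labels: nominal sampling times for the rich design, sampling-window
#' labels (day 1 / troughs) for the sparse design.
#'
#' @param fit A `pru_fit` object.
#' @param dataset The fitted dataset (observed records and design points).
#' @param n_sim Number of replicate simulations (>= 1).
#' @param seed Integer seed.
#' @param probs Percentiles to track (default 5th, 50th, 95th).
#' @param band Coverage of the across-replicate band (default 90%).
#' @return A tibble of class `pru_vpc`: one row per bin x percentile with
#'   the observed value and the simulated band (`sim_lo`, `sim_med`,
#'   `sim_hi`).
#' @export
vpc <- function(fit, dataset, n_sim = 200, seed = 1,
                probs = c(0.05, 0.5, 0.95), band = 0.9) {
  stopifnot(inherits(fit, "pru_fit"), n_sim >= 1)
  set.seed(seed)
  pop <- fit$pop
  obs <- dataset[dataset$evid == 0L, ]
  bins <- obs$visit
  if (all(is.na(bins))) bins <- sprintf("%gh", round(obs$time_h, 1))

  sim_one <- function() {
    dv <- purrr::map(fit$subjects, function(s) {
      if (s$n_obs == 0) return(numeric(0))
      om_cl <- pop$omega$cl[[s$study_label]]
      sig <- pop$sigma[[s$study_label]]
      eta <- c(rnorm(1, 0, om_cl), rnorm(1, 0, pop$omega$v2),
               rnorm(1, 0, pop$omega$v3))
      cl <- pop$cl_tv[[s$study_label]] * s$wt_cl * exp(eta[1])
      v2 <- pop$v2_tv * s$wt_v * exp(eta[2])
      v3 <- pop$v3_tv * s$wt_v * exp(eta[3])
      conc <- .conc_profile_cpp(cl, v2, pop$q_tv * s$wt_q, v3,
                                pop$ka1, pop$ka2, pop$mtime, pop$f1,
                                s$dose_times, s$dose_amts, s$obs_times)
      conc * exp(rnorm(length(conc), 0, sig))
    })
    unlist(dv)
  }

  pct_by_bin <- function(dv) {
    tibble::tibble(bin = bins, dv = dv) |>
      dplyr::group_by(.data$bin) |>
      dplyr::reframe(prob = probs,
                     value = quantile(.data$dv, probs, names = FALSE))
  }

  sims <- purrr::map_dfr(seq_len(n_sim), function(r) {
    dplyr::mutate(pct_by_bin(sim_one()), rep = r)
  })
  alpha <- (1 - band) / 2
  band_tbl <- sims |>
    dplyr::group_by(.data$bin, .data$prob) |>
    dplyr::summarise(sim_lo = quantile(.data$value, alpha, names = FALSE),
                     sim_med = quantile(.data$value, 0.5, names = FALSE),
                     sim_hi = quantile(.data$value, 1 - alpha,
                                       names = FALSE),
                     .groups = "drop")
  obs_tbl <- pct_by_bin(obs$dv_ng_per_ml) |>
    dplyr::rename(observed = "value")
  out <- dplyr::left_join(obs_tbl, band_tbl, by = c("bin", "prob"))
  class(out) <- c("pru_vpc", class(out))
  attr(out, "n_sim") <- n_sim
  out
}
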