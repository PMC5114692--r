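test_that("FOCE objective matches an adaptive-quadrature oracle on toy
           fixtures", {
  ds <- toy_dataset(c(0.25, -0.4), seed = 3)
  pop <- toy_pop()
  expect_lt(abs(foce_objective(pop, ds) - quad_ofv_oracle(pop, ds)), 0.5)
  # different variability settings
  pop2 <- toy_pop(om_cl = 0.6, sig = 0.35)
  expect_lt(abs(foce_objective(pop2, ds) - quad_ofv_oracle(pop2, ds)),
            0.5)
})

test_that("omega -> 0 reduces the objective to the fixed-effects
           lognormal -2LL", {
  ds <- toy_dataset(c(0, 0), seed = 4)
  pop0 <- population_model(omega = list(cl = c(rich = 0, sparse = 0),
                                        v2 = 0, v3 = 0),
                           sigma = c(rich = 0.2, sparse = 0.2))
  obs <- ds[ds$evid == 0L, ]
  f0 <- purrr::map_dfr(unique(ds$id), function(i) {
    p <- individual_parameters(pop0, list(age_years = 9, weight_kg = 30),
                               study = "rich")
    tibble::tibble(id = i,
                   f = solve_regimen(p, data.frame(time = 0, amount = 900),
                                     obs$time_h[obs$id == i])$conc_ng_per_ml)
  })
  r <- log(obs$dv_ng_per_ml) - log(f0$f)
  wls <- sum(log(2 * pi * 0.2^2) + r^2 / 0.2^2)
  expect_equal(foce_objective(pop0, ds), wls, tolerance = 1e-8)
})

test_that("a subject without observations is inert", {
  ds <- toy_dataset(c(0.1, -0.1), seed = 5)
  pop <- toy_pop()
  ofv <- foce_objective(pop, ds)
  empty <- make_dataset(ids = 99, obs_times = list(numeric(0)),
                        dv = list(numeric(0)), dose_ug = 900,
                        weight_kg = 30, age_years = 9)
  expect_equal(foce_objective(pop, dplyr::bind_rows(ds, empty)), ofv)
  eta <- estimate_ebe(pop, empty)
  expect_equal(as.numeric(eta), c(0, 0, 0))
  expect_true(isTRUE(attr(eta, "no_data")))
})

test_that("the conditional mode matches a 1-D optimisation oracle", {
  ds <- toy_dataset(0.35, seed = 6)
  pop <- toy_pop()
  eta_hat <- estimate_ebe(pop, ds)
  obs <- ds[ds$evid == 0L, ]
  g <- function(e) {
    p <- individual_parameters(pop, list(age_years = 9, weight_kg = 30),
                               eta = list(cl = e), study = "rich")
    f <- solve_regimen(p, data.frame(time = 0, amount = 900),
                       obs$time_h)$conc_ng_per_ml
    sum((log(obs$dv_ng_per_ml) - log(f))^2) / 0.2^2 + e^2 / 0.3^2
  }
  oracle <- stats::optimize(g, c(-2, 2), tol = 1e-10)$minimum
  expect_equal(unname(eta_hat["cl"]), oracle, tolerance = 1e-4)
})

test_that("with vanishing noise and rich sampling the EBEs recover the
           simulated random effects", {
  pop <- population_model(sigma = c(rich = 1e-4, sparse = 1e-4))
  eta_true <- list(cl = 0.25, v2 = -0.15, v3 = 0.2)
  p <- individual_parameters(pop, list(age_years = 9, weight_kg = 30),
                             eta = eta_true, study = "rich")
  times <- c(0.5, 1, 2, 3, 4, 6, 8, 12, 18, 24, 48, 72)
  f <- solve_regimen(p, data.frame(time = 0, amount = 900),
                     times)$conc_ng_per_ml
  ds <- make_dataset(ids = 1, obs_times = list(times), dv = list(f),
                     dose_ug = 900, weight_kg = 30, age_years = 9)
  eta_hat <- estimate_ebe(pop, ds)
  expect_equal(unname(eta_hat["cl"]), eta_true$cl, tolerance = 0.01)
  expect_equal(unname(eta_hat["v2"]), eta_true$v2, tolerance = 0.01)
  expect_equal(unname(eta_hat["v3"]), eta_true$v3, tolerance = 0.01)
})

test_that("self-consistency: starting at the truth with tiny noise the
           optimizer stays within 1%", {
  pop <- population_model(omega = list(cl = c(rich = 0, sparse = 0),
                                       v2 = 0, v3 = 0),
                          sigma = c(rich = 0.01, sparse = 0.01))
  d <- design_rich(6)
  ds <- simulate_trial(generate_cohort(d, seed = 7), d, pop, seed = 8)
  fit <- fit_population(filter_records(ds)$data, init = pop,
                        fixed_mask = c("om_cl_rich", "om_v2", "om_v3"),
                        se = FALSE, control = list(polish_maxit = 60))
  est <- setNames(fit$theta$estimate, fit$theta$term)
  expect_equal(est[["cl_rich"]], 22.9, tolerance = 0.01)
  expect_equal(est[["v2"]], 446, tolerance = 0.01)
  expect_equal(est[["q"]], 16.9, tolerance = 0.01)
  expect_equal(est[["v3"]], 248, tolerance = 0.01)
  expect_lte(fit$ofv, fit$ofv_init + 1e-8)
})

test_that("the returned optimum beats randomly perturbed starts", {
  pop <- population_model()
  d <- design_rich(8)
  ds <- simulate_trial(generate_cohort(d, seed = 9), d, pop, seed = 10)
  data <- filter_records(ds)$data
  fit <- fit_population(data, init = pop,
                        fixed_mask = c("q", "v3", "om_v3"),
                        se = FALSE, control = list(polish_maxit = 100))
  set.seed(11)
  for (k in 1:10) {
    pert <- pop
    for (nm in c("cl_rich", "v2", "om_cl_rich", "om_v2", "sig_rich")) {
      pert <- prucapop:::pop_set(pert, nm,
                                 prucapop:::pop_get(pert, nm) *
                                   runif(1, 0.7, 1.3))
    }
    expect_gte(foce_objective(pert, data), fit$ofv - 1e-6)
  }
})

test_that("shrinkage formula and degenerate cases", {
  pop <- population_model()
  set.seed(12)
  base <- rnorm(40)
  x <- (base - mean(base)) / sd(base) * 0.24 # sd exactly 0.24
  fake <- structure(list(
    pop = pop,
    ebe = tibble::tibble(id = 1:40, study = "rich", n_obs = 13,
                         eta_cl = x, eta_v2 = x, eta_v3 = x,
                         ofv_i = 0),
    details = list(), subjects = list()
  ), class = "pru_fit")
  shr <- compute_shrinkage(fake)
  cl_rich <- shr$eta$shrinkage_pct[shr$eta$parameter == "cl"]
  expect_equal(cl_rich, (1 - 0.24 / 0.30) * 100, tolerance = 1e-10)
  expect_equal(cl_rich, 20, tolerance = 1e-8)
  expect_true(is.na(shr$eps)) # no observations -> undefined
  # omega = 0 -> undefined eta shrinkage
  fake$pop <- population_model(omega = list(cl = c(rich = 0, sparse = 0),
                                            v2 = 0, v3 = 0))
  expect_true(all(is.na(compute_shrinkage(fake)$eta$shrinkage_pct)))
})

test_that("shrinkage grows as sampling becomes sparser", {
  pop <- population_model()
  d <- design_rich(25)
  coh <- generate_cohort(d, seed = 13)
  ds <- simulate_trial(coh, d, pop, seed = 14)
  full <- evaluate_population(pop, filter_records(ds)$data)
  # keep only two observations per subject
  thin <- ds[ds$evid == 1L | ds$time_h %in% c(24, 72), ]
  thin_fit <- evaluate_population(pop, filter_records(thin)$data)
  s_full <- full$shrinkage$shrinkage_pct[
    full$shrinkage$parameter == "cl"]
  s_thin <- thin_fit$shrinkage$shrinkage_pct[
    thin_fit$shrinkage$parameter == "cl"]
  expect_gt(s_thin, s_full)
})

test_that("post hoc exposure arithmetic at the reference subject", {
  pop <- population_model(omega = list(cl = c(rich = 0, sparse = 0),
                                       v2 = 0, v3 = 0),
                          sigma = c(rich = 0.1, sparse = 0.1))
  times <- c(2, 26)
  p <- typical_parameters(pop, 70, "sparse")
  f <- solve_regimen(p, data.frame(time = c(0, 24), amount = 2000),
                     times)$conc_ng_per_ml
  ds <- make_dataset(ids = 1, obs_times = list(times), dv = list(f),
                     dose_time = c(0, 24), dose_ug = 2000,
                     study = "sparse", weight_kg = 70, age_years = 10)
  fit <- evaluate_population(pop, ds)
  pe <- posthoc_exposure(fit, ds)
  expect_equal(pe$subjects$cl_i, 20.1, tolerance = 1e-6)
  expect_equal(pe$subjects$auc, 0.858 * 2000 / 20.1, tolerance = 1e-6)
  expect_equal(pe$subjects$auc, 85.37, tolerance = 1e-3)
  expect_equal(pe$subjects$css, pe$subjects$auc / 24)
  # AUC is strictly decreasing in clearance at fixed dose
  expect_true(all(diff(0.858 * 2000 / seq(5, 40, 5)) < 0))
})
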