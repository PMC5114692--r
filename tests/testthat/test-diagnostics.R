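test_that("CWRES are identically zero when the data match the typical
           prediction exactly", {
  d <- design_rich(4)
  pop0 <- population_model(omega = list(cl = c(rich = 0, sparse = 0),
                                        v2 = 0, v3 = 0),
                           sigma = c(rich = 0, sparse = 0))
  ds <- simulate_trial(generate_cohort(d, seed = 1), d, pop0, seed = 2)
  fit <- evaluate_population(population_model(), filter_records(ds)$data)
  res <- compute_cwres(fit, filter_records(ds)$data)
  expect_lt(max(abs(res$cwres)), 1e-8)
  expect_lt(max(abs(res$iwres)), 1e-8)
  expect_equal(res$pred, res$ipred, tolerance = 1e-10)
})

test_that("CWRES are approximately standard normal under the generating
           model", {
  pop <- population_model()
  d <- design_rich(80)
  ds <- simulate_trial(generate_cohort(d, seed = 3), d, pop, seed = 4)
  data <- filter_records(ds)$data
  fit <- evaluate_population(pop, data)
  res <- compute_cwres(fit, data)
  expect_gte(nrow(res), 400)
  expect_lt(abs(mean(res$cwres)), 0.1)
  expect_gt(sd(res$cwres), 0.9)
  expect_lt(sd(res$cwres), 1.1)
})

test_that("CWRES match a hand-built linearisation oracle on a single
           subject", {
  pop <- population_model()
  ds <- toy_dataset(0.3, sig = 0.14, seed = 5)
  data <- filter_records(ds)$data
  fit <- evaluate_population(pop, data)
  res <- compute_cwres(fit, data)
  obs <- data[data$evid == 0L, ]
  # independent R-side linearisation
  eta_hat <- fit$details[[1]]$eta
  logf <- function(eta) {
    p <- individual_parameters(pop, list(age_years = 9, weight_kg = 30),
                               eta = list(cl = eta[1], v2 = eta[2],
                                          v3 = eta[3]), study = "rich")
    log(solve_regimen(p, data.frame(time = 0, amount = 900),
                      obs$time_h)$conc_ng_per_ml)
  }
  h <- 1e-5
  G <- sapply(1:3, function(k) {
    e1 <- eta_hat; e2 <- eta_hat
    e1[k] <- e1[k] + h; e2[k] <- e2[k] - h
    (logf(e1) - logf(e2)) / (2 * h)
  })
  om <- c(pop$omega$cl[["rich"]], pop$omega$v2, pop$omega$v3)
  C <- G %*% diag(om^2) %*% t(G) + diag(pop$sigma[["rich"]]^2, 3)
  r <- log(obs$dv_ng_per_ml) - logf(eta_hat) + as.numeric(G %*% eta_hat)
  oracle <- forwardsolve(t(chol(C)), r)
  expect_equal(res$cwres, oracle, tolerance = 1e-5)
})

test_that("diagnostics do not mutate the dataset or fit, and the Q-Q
           table is a pure function of the residuals", {
  pop <- population_model()
  d <- design_rich(6)
  ds <- simulate_trial(generate_cohort(d, seed = 6), d, pop, seed = 7)
  data <- filter_records(ds)$data
  fit <- evaluate_population(pop, data)
  snap_data <- as.data.frame(data)
  snap_ofv <- fit$ofv
  res <- compute_cwres(fit, data)
  qq <- cwres_qq(res)
  expect_equal(as.data.frame(data), snap_data)
  expect_equal(fit$ofv, snap_ofv)
  expect_equal(qq$cwres_ordered, sort(res$cwres))
  expect_equal(nrow(qq), nrow(res))
  expect_equal(cwres_qq(res), qq)
})

test_that("VPC behaves as specified in degenerate and stochastic cases", {
  pop <- population_model()
  d <- design_rich(25)
  ds <- simulate_trial(generate_cohort(d, seed = 8), d, pop, seed = 9)
  data <- filter_records(ds)$data
  fit <- evaluate_population(pop, data)
  # n_sim = 1: bands collapse onto that replicate
  v1 <- vpc(fit, data, n_sim = 1, seed = 10)
  expect_equal(v1$sim_lo, v1$sim_med)
  expect_equal(v1$sim_med, v1$sim_hi)
  # self-consistency: observed median inside the 90% band of the median
  # in most bins (nominal per-bin coverage is 90%)
  v <- vpc(fit, data, n_sim = 150, seed = 11)
  med <- v[v$prob == 0.5, ]
  cover <- mean(med$observed >= med$sim_lo & med$observed <= med$sim_hi)
  expect_gte(cover, 0.8)
  # inflating the clearance IIV widens every median band
  pop3 <- population_model(omega = list(cl = c(rich = 0.9, sparse = 1.8),
                                        v2 = 0.4, v3 = 0.5))
  fit3 <- evaluate_population(pop3, data)
  v3 <- vpc(fit3, data, n_sim = 150, seed = 11)
  m <- v[v$prob == 0.5, ]
  m3 <- v3[v3$prob == 0.5, ]
  w <- m$sim_hi - m$sim_lo
  w3 <- m3$sim_hi - m3$sim_lo
  # clearance variability dominates band width from the distribution
  # phase onward; during absorption (< 3 h) its effect is within
  # Monte-Carlo noise, so the monotone-widening claim applies to the
  # elimination-phase bins
  late <- m$bin %in% c("6h", "8h", "12h", "18h", "24h", "48h", "72h")
  expect_true(all(w3[late] > 1.4 * w[late]))
  expect_gte(mean(w3 >= 0.95 * w), 0.9)
})
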