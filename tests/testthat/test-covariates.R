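test_that("postmenstrual age follows the 40-week-offset definition", {
  expect_equal(compute_pma(0), 40)
  expect_equal(compute_pma(2), 2 * 365.25 / 7 + 40)
  expect_equal(compute_pma(2), 144.36, tolerance = 1e-4)
  ages <- seq(0, 18, by = 0.5)
  expect_true(all(diff(compute_pma(ages)) > 0))
  expect_error(compute_pma(-1), ">= 0")
})

test_that("creatinine clearance formula and proportionalities", {
  # at 70 kg the weight factor is exactly 1
  expect_equal(compute_crcl(150, 50, 70), 42.5 * 150 / 50)
  expect_equal(compute_crcl(130, 40, 27.9), 72.5, tolerance = 1e-3)
  expect_equal(compute_crcl(130, 80, 27.9),
               compute_crcl(130, 40, 27.9) / 2)
  expect_error(compute_crcl(130, 0, 30), "> 0")
})

test_that("renal maturation is a Hill curve clamped after 24 months", {
  expect_equal(maturation_gfr(47.7), 0.5)
  pma24 <- 24 * 365.25 / 12 / 7 + 40
  raw24 <- pma24^3.4 / (47.7^3.4 + pma24^3.4)
  expect_gte(raw24, 0.975)
  # clamp step at the 24-month boundary is bounded by 2.5%
  expect_lt(maturation_gfr(pma24 + 1e-6) - maturation_gfr(pma24), 0.025)
  expect_equal(maturation_gfr(compute_pma(10)), 1)
  pma <- seq(30, 140, by = 5)
  expect_true(all(diff(maturation_gfr(pma)) > 0))
  expect_true(all(maturation_gfr(pma) < 1))
})

test_that("individual parameters reproduce typical values at reference
           size and the allometric worked examples", {
  pop <- population_model()
  p70 <- individual_parameters(pop, list(age_years = 10, weight_kg = 70),
                               study = "rich")
  expect_equal(p70$cl, 22.9)
  expect_equal(p70$v2, 446)
  expect_equal(p70$q, 16.9)
  expect_equal(p70$v3, 248)
  p24 <- individual_parameters(pop, list(age_years = 10, weight_kg = 24),
                               study = "sparse")
  expect_equal(p24$cl, 20.1 * (24 / 70)^0.75)
  expect_equal(p24$cl, 9.00, tolerance = 1e-3)
  p279 <- individual_parameters(pop, list(age_years = 10,
                                          weight_kg = 27.9),
                                study = "rich")
  expect_equal(p279$cl, 11.49, tolerance = 1e-3)
  # volumes scale with power 1: per-kg volume preserved exactly
  expect_equal(p24$v2 / 24, 446 / 70)
  expect_equal(p24$v3 / 24, 248 / 70)
  # random effects act multiplicatively
  pe <- individual_parameters(pop, list(age_years = 10, weight_kg = 24),
                              eta = list(cl = 0.2), study = "sparse")
  expect_equal(pe$cl, p24$cl * exp(0.2))
  expect_error(individual_parameters(pop, list(age_years = 10,
                                               weight_kg = 24),
                                     study = "nope"), "unknown study")
})

test_that("derived covariates are recomputed and not trusted from input", {
  cov <- tibble::tibble(age_years = c(2, 8), weight_kg = c(12, 26),
                        height_cm = c(87, 128), scr_umol_l = c(26, 37),
                        pma_weeks = c(-1, -1), crcl_ml_min = c(-1, -1))
  out <- derive_covariates(cov)
  expect_equal(out$pma_weeks, compute_pma(c(2, 8)))
  expect_equal(out$crcl_ml_min,
               compute_crcl(c(87, 128), c(26, 37), c(12, 26)))
})

test_that("simulated random effects show no residual trend against
           covariates after allometric scaling", {
  set.seed(42)
  d <- design_sparse(500)
  coh <- generate_cohort(d, n = 500, seed = 42)
  eta <- rnorm(500, 0, 0.6)
  # individual CL divided by its covariate prediction isolates exp(eta)
  pop <- population_model()
  cl_i <- vapply(seq_len(500), function(k) {
    individual_parameters(pop, coh[k, ], eta = list(cl = eta[k]),
                          study = "sparse")$cl
  }, numeric(1))
  resid <- log(cl_i) - 0.75 * log(coh$weight_kg / 70) -
    log(maturation_gfr(coh$pma_weeks))
  for (v in list(coh$weight_kg, coh$age_years, coh$crcl_ml_min)) {
    expect_lt(abs(cor(resid, v, method = "spearman")), 0.15)
  }
})

test_that("missing covariates are imputed from study medians,
           deterministically", {
  cov <- tibble::tibble(
    study = c("rich", "rich", "rich", "sparse", "sparse"),
    age_years = c(6, 8, 10, 5, 9),
    weight_kg = c(20, NA, 32, 18, NA),
    height_cm = c(115, 128, NA, 109, 133),
    scr_umol_l = c(33, 37, 41, NA, 39))
  out <- impute_covariates(cov)
  expect_equal(out$weight_kg[2], median(c(20, 32)))
  expect_equal(out$weight_kg[5], 18)
  expect_equal(out$height_cm[3], median(c(115, 128)))
  expect_equal(out$scr_umol_l[4], 39)
  expect_false(any(is.na(out$crcl_ml_min)))
  expect_identical(out, impute_covariates(cov))
  cov$age_years[1] <- NA
  expect_error(impute_covariates(cov), "age_years must be observed")
})
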