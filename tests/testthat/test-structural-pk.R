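test_that("closed-form profile matches a high-accuracy stiff-ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- typical_rich_params()
  tt <- c(0.25, 0.5, 0.734, 1, 2, 4, 8, 12, 24, 48, 72)
  mine <- solve_regimen(p, data.frame(time = 0, amount = 2000),
                        tt)$conc_ng_per_ml
  oracle <- ode_conc_oracle(p, 2000, tt)
  expect_lt(max(abs(mine - oracle) / oracle), 1e-8)
  # frozen oracle value at t = 2 h for a 2000 ug dose at 70 kg typicals
  expect_equal(mine[tt == 2], 3.42041, tolerance = 1e-5)
})

test_that("profile is zero before dosing and for zero amounts", {
  p <- typical_rich_params()
  prof <- solve_regimen(p, data.frame(time = 10, amount = 2000),
                        c(0, 2, 5, 9.999, 10))
  expect_true(all(prof$conc_ng_per_ml == 0))
  prof0 <- solve_regimen(p, data.frame(time = 0, amount = 0),
                         seq(0, 24, 1))
  expect_true(all(prof0$conc_ng_per_ml == 0))
})

test_that("profiles are exactly linear in dose and superpose over doses", {
  p <- typical_rich_params()
  tt <- seq(0, 96, by = 0.5)
  one <- solve_regimen(p, data.frame(time = 0, amount = 1000), tt)
  two <- solve_regimen(p, data.frame(time = 0, amount = 2000), tt)
  expect_equal(two$conc_ng_per_ml, 2 * one$conc_ng_per_ml,
               tolerance = 1e-12)
  multi <- solve_regimen(p, data.frame(time = c(0, 24, 48),
                                       amount = c(1000, 500, 2000)), tt)
  shifted <- function(amt, t0) {
    solve_regimen(p, data.frame(time = t0, amount = amt),
                  tt)$conc_ng_per_ml
  }
  expect_equal(multi$conc_ng_per_ml,
               shifted(1000, 0) + shifted(500, 24) + shifted(2000, 48),
               tolerance = 1e-10)
})

test_that("with ka1 = ka2 the absorption switch is inert", {
  base <- pk_params(cl = 20.1, v2 = 446, q = 16.9, v3 = 248,
                    ka1 = 1.3, ka2 = 1.3, mtime = 0.734)
  noswitch <- pk_params(cl = 20.1, v2 = 446, q = 16.9, v3 = 248,
                        ka1 = 1.3, ka2 = 1.3, mtime = 0)
  tt <- seq(0, 48, by = 0.25)
  d <- data.frame(time = 0, amount = 1500)
  expect_equal(solve_regimen(base, d, tt)$conc_ng_per_ml,
               solve_regimen(noswitch, d, tt)$conc_ng_per_ml,
               tolerance = 1e-10)
})

test_that("mass balance holds to 0.01% at all times, multi-dose included", {
  p <- typical_rich_params()
  doses <- data.frame(time = c(0, 24, 48), amount = c(2000, 2000, 2000))
  tt <- seq(0.1, 96, by = 0.7)
  am <- regimen_amounts(p, doses, tt)
  dosed <- p$f1 * vapply(tt, function(t) {
    sum(doses$amount[doses$time < t])
  }, numeric(1))
  total <- am$depot + am$central + am$peripheral + am$eliminated
  expect_lt(max(abs(total - dosed) / dosed), 1e-4)
})

test_that("steady-state AUC equals f1 * dose / cl and matches explicit
           superposition of daily doses", {
  p <- pk_params(cl = 20.1, v2 = 446, q = 16.9, v3 = 248)
  ss <- steady_state_profile(p, 2000, 24, dt = 0.05)
  m <- exposure_metrics(ss, 24, f1 = 0.858, dose = 2000, cl = 20.1)
  expect_equal(m$auc_tau, 0.858 * 2000 / 20.1, tolerance = 1e-3)
  expect_equal(0.858 * 2000 / 20.1, 85.373, tolerance = 1e-4)
  # explicit 14-dose superposition over the final interval
  n <- 14
  grid <- seq(0, 24, by = 0.05)
  conc14 <- solve_regimen(
    p, data.frame(time = (seq_len(n) - 1) * 24, amount = rep(2000, n)),
    (n - 1) * 24 + grid)$conc_ng_per_ml
  expect_lt(max(abs(conc14 - ss$conc_ng_per_ml) /
                  pmax(ss$conc_ng_per_ml, 1e-9)), 1e-3)
})

test_that("a single dose with huge interval reduces to the single-dose
           profile", {
  p <- typical_rich_params()
  ss <- steady_state_profile(p, 1000, 2000, dt = 1)
  single <- solve_regimen(p, data.frame(time = 0, amount = 1000),
                          seq(0, 2000, by = 1))
  expect_equal(ss$conc_ng_per_ml, single$conc_ng_per_ml,
               tolerance = 1e-10)
})

test_that("exposure metrics: constant profile, ordering, and arithmetic", {
  const <- structure(tibble::tibble(time_h = seq(0, 24, 0.5),
                                    conc_ng_per_ml = 3.3),
                     class = c("pk_profile", "tbl_df", "tbl",
                               "data.frame"))
  m <- exposure_metrics(const, 24)
  expect_equal(m$auc_tau, 3.3 * 24)
  expect_equal(m$cmax, 3.3)
  expect_equal(m$cmin, 3.3)
  expect_equal(m$css, 3.3)
  expect_equal(m$c0h, 3.3)
  # individual post hoc arithmetic: cl 9.0, dose 960 ug, f1 0.858
  expect_equal(0.858 * 960 / 9.0, 91.52, tolerance = 1e-4)
  p <- typical_rich_params()
  ss <- steady_state_profile(p, 2000, 24, dt = 0.05)
  m2 <- exposure_metrics(ss, 24, 0.858, 2000, p$cl)
  expect_true(m2$cmin <= m2$css && m2$css <= m2$cmax)
  # sparse grid triggers the AUC discrepancy warning
  sparse <- structure(ss[seq(1, nrow(ss), by = 120), ],
                      class = class(ss))
  expect_warning(exposure_metrics(sparse, 24, 0.858, 2000, p$cl),
                 "grid may be too sparse")
})

test_that("invalid parameters and inputs are rejected", {
  expect_error(pk_params(cl = -1, v2 = 446, q = 16.9, v3 = 248),
               "strictly positive")
  expect_error(pk_params(cl = Inf, v2 = 446, q = 16.9, v3 = 248),
               "finite")
  expect_error(pk_params(cl = 20, v2 = 446, q = 16.9, v3 = 248, f1 = 1.2),
               "f1")
  p <- typical_rich_params()
  expect_error(solve_regimen(p, data.frame(time = 0, amount = -5), 1:3),
               ">= 0")
  expect_error(solve_regimen(p, data.frame(time = 0, amount = 5),
                             c(3, 1, 2)), "sorted")
})
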