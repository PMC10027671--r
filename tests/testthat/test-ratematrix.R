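test_that("a single captured state gives the plain exponential density", {
  sch <- hsumo_scheme()
  f <- dwell_pdf(sch, "captured", concentration = 65e-9)
  t <- seq(0, 0.1, length.out = 50)
  expect_equal(f(t), 74.5 * exp(-74.5 * t), tolerance = 1e-12)
  g <- dwell_pdf(sch, "released", concentration = 65e-9)
  r <- 1.12e8 * 65e-9
  expect_equal(g(t), r * exp(-r * t), tolerance = 1e-12)
})

test_that("without interconversion the captured density is the entry-flux mixture", {
  sch <- egfr_scheme()
  f <- dwell_pdf(sch, "captured", concentration = 40e-9)
  w <- c(6.62e7, 2.89e7) / (6.62e7 + 2.89e7)
  t <- seq(1e-4, 8, length.out = 400)
  ref <- w[1] * 12 * exp(-12 * t) + w[2] * 1.01 * exp(-1.01 * t)
  expect_lt(max(abs(f(t) - ref)), 1e-10)
})

test_that("rate-matrix densities are normalized and consistent with their CDFs", {
  for (sch in list(hsumo_scheme(), egfr_scheme(), egfr_ic_scheme(20, 20))) {
    f <- dwell_pdf(sch, "captured", concentration = 40e-9)
    cdf <- dwell_cdf(sch, "captured", concentration = 40e-9)
    tmax <- 50 * 1  # 50x the slowest time constant (~1 s)
    expect_equal(integrate(f, 0, tmax, rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-6)
    # numeric integral of f matches the CDF
    expect_equal(integrate(f, 0, 0.5, rel.tol = 1e-10)$value, cdf(0.5),
                 tolerance = 1e-8)
    expect_equal(cdf(0), 0, tolerance = 1e-12)
  }
})

test_that("rate-matrix density agrees with Gillespie dwell histograms", {
  # quick version of the simulation cross-check (the acceptance suite runs
  # the full-size one)
  sch <- egfr_ic_scheme(20, 20)
  path <- simulate_dwells(sch, 40e-9, 4000, seed = 13)
  cc <- collapse_classes(path)
  cap <- cc$duration_s[cc$class == "captured" & !cc$censored]
  expect_gt(length(cap), 3000)
  cdf <- dwell_cdf(sch, "captured", concentration = 40e-9)
  expect_gt(ks.test(cap, cdf)$p.value, 0.01)
})

test_that("two_mode fitting recovers the generator rates", {
  sch <- egfr_scheme()
  path <- simulate_dwells(sch, 40e-9, 1000, seed = 17)
  cc <- collapse_classes(path)
  m <- fit_scheme(cc, "two_mode", 40e-9)
  est <- tidy(m)$estimate
  truth <- c(6.62e7, 2.89e7, 12.0, 1.01)
  expect_true(all(abs(est - truth) / truth < 0.12))
})

test_that("interconversion rates collapse to zero on independent-substate data", {
  sch <- egfr_scheme()
  path <- simulate_dwells(sch, 40e-9, 800, seed = 19)
  cc <- collapse_classes(path)
  m <- fit_scheme(cc, "interconversion", 40e-9)
  r <- m$scheme$rates
  k12 <- r$rate[r$from == "O_off1" & r$to == "O_off2"]
  k21 <- r$rate[r$from == "O_off2" & r$to == "O_off1"]
  koff1 <- r$rate[r$from == "O_off1" & r$to == "O_on"]
  expect_lt(k12, 0.05 * koff1)
  expect_lt(k21, 0.05 * koff1)
})

test_that("scheme comparison applies the strict chi-squared decision rule", {
  sch <- egfr_scheme()
  path <- simulate_dwells(sch, 40e-9, 300, seed = 23)
  cc <- collapse_classes(path)
  m <- fit_scheme(cc, "two_mode", 40e-9)
  # identical models: 2 dlogL = 0, never superior
  same <- compare_schemes(m, m)
  expect_equal(same$llr, 0)
  expect_false(same$superior)

  # boundary case at df = 2: 5.99 < qchisq(0.95, 2) = 5.9915
  m_lo <- porekin:::rate_matrix_model(m$scheme, 40e-9, logL = 0,
                                      n_params = 4L, topology = "two_mode")
  m_hi <- porekin:::rate_matrix_model(m$scheme, 40e-9, logL = 5.99 / 2,
                                      n_params = 6L,
                                      topology = "interconversion")
  cmp <- compare_schemes(m_lo, m_hi)
  expect_equal(cmp$df, 2)
  expect_false(cmp$superior)
  m_hi2 <- porekin:::rate_matrix_model(m$scheme, 40e-9, logL = 3.1,
                                       n_params = 6L,
                                       topology = "interconversion")
  expect_true(compare_schemes(m_lo, m_hi2)$superior)

  # reversed nesting order is a usage error
  expect_error(compare_schemes(m_hi, m_lo), "nested")
})

test_that("the bimolecular fit matches closed-form rate estimates", {
  sch <- hsumo_scheme()
  path <- simulate_dwells(sch, 130e-9, 120, seed = 29)
  cc <- collapse_classes(path)
  m <- fit_scheme(cc, "bimolecular", 130e-9)
  est <- tidy(m)$estimate
  rel <- cc$duration_s[cc$class == "released" & !cc$censored]
  cap <- cc$duration_s[cc$class == "captured" & !cc$censored]
  expect_equal(est[1], 1 / (130e-9 * mean(rel)), tolerance = 1e-10)
  expect_equal(est[2], 1 / mean(cap), tolerance = 1e-10)
})
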