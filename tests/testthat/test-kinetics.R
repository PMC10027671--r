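test_that("through-origin slope reproduces the reported association constant", {
  ser <- concentration_series(c(65e-9, 130e-9, 260e-9),
                              tau_on_s = c(0.125, 0.069, 0.035),
                              tau_off_s = c(0.015, 0.016, 0.014))
  kon <- fit_kon(ser)
  expect_equal(kon$k_on_M1s1, 1.108216e8, tolerance = 1e-4)
  # free-intercept diagnostic is reported
  expect_true(is.finite(kon$intercept_s1))

  # exact proportional data: slope recovered to machine precision
  s <- 2e8
  ser2 <- concentration_series(c(1e-9, 5e-9, 2e-8), tau_on_s = 1 / (s * c(1e-9, 5e-9, 2e-8)))
  expect_equal(suppressWarnings(fit_kon(ser2))$k_on_M1s1, s,
               tolerance = 1e-12)  # lm warns on the exact fit

  # single entry falls back to 1/(C tau) with a warning
  ser1 <- concentration_series(65e-9, tau_on_s = 0.125)
  expect_warning(k1 <- fit_kon(ser1), "single concentration")
  expect_equal(k1$k_on_M1s1, 1 / (65e-9 * 0.125), tolerance = 1e-12)
})

test_that("k_off is the mean reciprocal captured duration across the series", {
  ser <- concentration_series(c(65e-9, 130e-9, 260e-9),
                              tau_on_s = c(0.125, 0.069, 0.035),
                              tau_off_s = c(0.015, 0.016, 0.014))
  koff <- fit_koff(ser)
  expect_equal(koff$k_off_s1, mean(1 / c(0.015, 0.016, 0.014)),
               tolerance = 1e-12)
  expect_equal(koff$k_off_s1, 66.865, tolerance = 1e-4)

  # identical durations: zero scatter
  ser_c <- concentration_series(c(1e-8, 2e-8), tau_on_s = c(0.1, 0.05),
                                tau_off_s = c(0.02, 0.02))
  kc <- fit_koff(ser_c)
  expect_equal(kc$k_off_s1, 50)
  expect_equal(kc$se_s1, 0)
})

test_that("K_D arithmetic reproduces the published equilibrium constants", {
  expect_equal(compute_kd(1.12e8, 74.5)$kd_nM, 665.18, tolerance = 1e-4)
  expect_equal(compute_kd(6.62e7, 12.0)$kd_nM, 181.27, tolerance = 1e-4)
  expect_equal(compute_kd(1, 1)$kd_M, 1)
  # error propagation: relative variances add
  kd_half <- compute_kd(1e8, 50, se_k_off = 5)
  expect_equal(kd_half$se_M / kd_half$kd_M, 0.1, tolerance = 1e-12)
  kd <- compute_kd(1e8, 50, se_k_on = 1e7, se_k_off = 5)
  expect_equal(kd$se_M / kd$kd_M, sqrt(0.01 + 0.01), tolerance = 1e-12)
  expect_error(compute_kd(0, 1), "positive")
})

test_that("mode probabilities carry binomial uncertainty", {
  ev <- tibble::tibble(class = "captured",
                       mode = rep(c(1L, 2L), c(720, 280)),
                       duration_s = 0.1, censored = FALSE,
                       start_s = 1:1000, mean_current_pA = 0,
                       blockade_fraction = 0.7)
  p <- mode_probabilities(ev)
  expect_equal(p$p, c(0.72, 0.28))
  expect_equal(p$se, rep(sqrt(0.72 * 0.28 / 1000), 2), tolerance = 1e-12)

  ev1 <- ev
  ev1$mode <- 1L
  expect_equal(mode_probabilities(ev1)$p, 1)
})

test_that("per-mode interevent durations invert to per-mode rate constants", {
  sch <- egfr_scheme()
  path <- simulate_dwells(sch, 40e-9, 1200, seed = 41)
  cc <- collapse_classes(path)
  # entry probability ratio ~ k_on1/(k_on1 + k_on2) = 0.696
  p1 <- mean(cc$mode[cc$class == "captured" & !cc$censored] == 1)
  expect_lt(abs(p1 - 6.62 / 9.51), 3 * sqrt(0.7 * 0.3 / 1500))
  tau <- mode_interevent_tau(cc)
  for (m in 1:2) {
    kon_m <- c(6.62e7, 2.89e7)[m]
    expected <- 1 / (kon_m * 40e-9)
    got <- tau$tau_on_s[tau$mode == m]
    expect_lt(abs(got - expected) / expected, 0.1)
  }
})

test_that("quantification inverts the calibrated frequency relation", {
  q <- estimate_concentration(tau_on = 1.7, k_on = 2.9e7)
  expect_equal(q$concentration_nM, 20.284, tolerance = 1e-4)
  expect_equal(estimate_concentration(1 / 2.9e7, 2.9e7)$concentration_M, 1)
  qe <- estimate_concentration(1.7, 2.9e7, se_tau_on = 0.5, se_k_on = 2e6)
  expect_equal(qe$se_M / qe$concentration_M,
               sqrt((0.5 / 1.7)^2 + (2e6 / 2.9e7)^2), tolerance = 1e-12)
  expect_error(estimate_concentration(-1, 1e7), "positive")

  # closed loop: simulated 20 nM two-mode data, calibrated k_on2
  sch <- egfr_scheme()
  path <- simulate_dwells(sch, 20e-9, 1500, seed = 43)
  cc <- collapse_classes(path)
  tau <- mode_interevent_tau(cc)
  est <- estimate_concentration(tau$tau_on_s[tau$mode == 2], 2.89e7,
                                se_tau_on = tau$se_s[tau$mode == 2])
  expect_lt(abs(est$concentration_nM - 20), 3 * est$se_nM)
})

test_that("conductance worked examples and kinetics summary invariances", {
  expect_equal(conductance(32.1, 40), 0.8025)
  expect_equal(conductance(39.5, 40), 0.9875)
  expect_equal(conductance(0, 40), 0)
  expect_error(conductance(10, 0), "non-zero")

  ser <- concentration_series(c(65e-9, 130e-9, 260e-9),
                              tau_on_s = c(0.125, 0.069, 0.035),
                              tau_off_s = c(0.015, 0.016, 0.014))
  ks1 <- kinetics_summary(ser)
  ks2 <- kinetics_summary(ser[c(3, 1, 2), ])
  expect_equal(ks1$kd_M, ks2$kd_M)
  expect_equal(ks1$k_on_M1s1, ks2$k_on_M1s1)
  expect_equal(ks1$kd_M, ks1$k_off_s1 / ks1$k_on_M1s1)
})
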