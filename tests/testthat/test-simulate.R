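test_that("zero concentration yields a single censored released dwell", {
  path <- simulate_dwells(hsumo_scheme(), 0, duration = 5, seed = 1)
  expect_equal(nrow(path), 1)
  expect_equal(path$class, "released")
  expect_true(path$censored)
  expect_equal(path$duration_s, 5)
})

test_that("dwell durations follow the analytic exponentials", {
  # k_on * C = 10 s^-1 at 1.12e8 M^-1 s^-1
  conc <- 10 / 1.12e8
  path <- simulate_dwells(hsumo_scheme(), conc, duration = 1200, seed = 42)
  rel <- path$duration_s[path$class == "released" & !path$censored]
  cap <- path$duration_s[path$class == "captured" & !path$censored]
  expect_gt(length(rel), 1e4)
  # sample mean within 3 standard errors of 1/10 s
  expect_lt(abs(mean(rel) - 0.1), 3 * 0.1 / sqrt(length(rel)))
  expect_lt(abs(mean(cap) - 1 / 74.5), 3 * (1 / 74.5) / sqrt(length(cap)))
  # KS against the analytic exponentials at alpha = 0.01
  expect_gt(ks.test(rel, "pexp", rate = 10)$p.value, 0.01)
  expect_gt(ks.test(cap, "pexp", rate = 74.5)$p.value, 0.01)
})

test_that("per-state dwells of the three-state scheme are exponential", {
  sch <- egfr_ic_scheme(20, 20)
  q <- generator_matrix(sch, 40e-9)
  path <- simulate_dwells(sch, 40e-9, duration = 4000, seed = 7)
  for (s in c("O_off1", "O_off2")) {
    dw <- path$duration_s[path$state == s & !path$censored]
    expect_gt(length(dw), 1000)
    expect_gt(ks.test(dw, "pexp", rate = -q[s, s])$p.value, 0.01)
  }
})

test_that("doubling concentration doubles the released-event frequency", {
  p1 <- simulate_dwells(hsumo_scheme(), 65e-9, duration = 400, seed = 3)
  p2 <- simulate_dwells(hsumo_scheme(), 130e-9, duration = 400, seed = 4)
  m1 <- mean(p1$duration_s[p1$class == "released" & !p1$censored])
  m2 <- mean(p2$duration_s[p2$class == "released" & !p2$censored])
  n1 <- sum(p1$class == "released" & !p1$censored)
  n2 <- sum(p2$class == "released" & !p2$censored)
  ratio <- m1 / m2
  se <- ratio * sqrt(1 / n1 + 1 / n2)
  expect_lt(abs(ratio - 2), 3 * se)
})

test_that("long-run captured occupancy matches the two-state closed form", {
  # k_on * C = 7.28 s^-1 (65 nM), k_off = 74.5: occupancy 0.0890
  path <- simulate_dwells(hsumo_scheme(), 65e-9, duration = 600, seed = 11)
  occ <- sum(path$duration_s[path$class == "captured"]) /
    sum(path$duration_s)
  expect_lt(abs(occ - 7.28 / (7.28 + 74.5)), 0.01)
})

test_that("simulation and rendering are bit-identical under a fixed seed", {
  sch <- hsumo_scheme()
  p1 <- simulate_dwells(sch, 130e-9, 5, seed = 99)
  p2 <- simulate_dwells(sch, 130e-9, 5, seed = 99)
  expect_identical(p1$duration_s, p2$duration_s)
  expect_identical(p1$state, p2$state)
  cfg <- trace_config(duration = 5, noise_sigma = 1, flicker_amplitude = 0.05,
                      seed = 5)
  t1 <- render_trace(p1, sch, cfg)
  t2 <- render_trace(p2, sch, cfg)
  expect_identical(t1$current_pA, t2$current_pA)
})

test_that("noiseless unfiltered rendering reproduces the state levels exactly", {
  sch <- hsumo_scheme()
  path <- manual_path(c(0.01, 0.005, 0.01))
  cfg <- trace_config(noise_sigma = 0, filter_cutoff = 0, duration = 0.025)
  tr <- render_trace(path, sch, cfg)
  expect_true(all(tr$current_pA %in% c(32.1, 2.9)))
  # level at each sample matches the state occupying that time
  tvec <- (seq_along(tr$current_pA) - 0.5) * tr$dt
  expected <- ifelse(tvec >= 0.01 & tvec < 0.015, 2.9, 32.1)
  expect_equal(tr$current_pA, expected)
})

test_that("white-noise rendering has the configured standard deviation", {
  sch <- hsumo_scheme()
  path <- manual_path(2, states = "O_on")
  cfg <- trace_config(noise_sigma = 1.5, filter_cutoff = 0, duration = 2,
                      seed = 8)
  tr <- render_trace(path, sch, cfg)
  n <- length(tr$current_pA)
  se_sd <- 1.5 / sqrt(2 * (n - 1))
  expect_lt(abs(sd(tr$current_pA) - 1.5), 3 * se_sd)
  expect_lt(abs(mean(tr$current_pA) - 32.1), 3 * 1.5 / sqrt(n))
})

test_that("the digital Bessel filter has the textbook rise time", {
  for (fc in c(1000, 3000)) {
    tr <- filter_rise_time(50000, fc)
    expect_lt(abs(tr - 0.3321 / fc) / (0.3321 / fc), 0.1)
  }
})

test_that("collapse_classes aggregates substate visits into class dwells", {
  sch <- egfr_ic_scheme(20, 20)
  path <- simulate_dwells(sch, 40e-9, duration = 50, seed = 2)
  cc <- collapse_classes(path)
  expect_true(all(cc$class == rep(c("released", "captured"),
                                  length.out = nrow(cc))))
  expect_equal(sum(cc$duration_s), sum(path$duration_s))
  # entry modes recorded for captured dwells
  expect_true(all(cc$mode[cc$class == "captured"] %in% 1:2))
  expect_true(all(cc$mode[cc$class == "released"] == 0))
})
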