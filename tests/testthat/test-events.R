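test_that("baseline estimation recovers the open-substate current", {
  sch <- hsumo_scheme()
  # constant open level + Gaussian noise
  path <- manual_path(2, states = "O_on")
  tr <- render_trace(path, sch, trace_config(noise_sigma = 1,
                                             filter_cutoff = 0,
                                             duration = 2, seed = 21))
  bl <- estimate_baseline(tr)
  expect_lt(abs(bl$i0 - 32.1), 0.05)
  expect_lt(abs(bl$sigma - 1), 0.1)

  # noiseless constant trace: exact level, zero width
  tr0 <- structure(list(current_pA = rep(18.2, 60000), dt = 1 / 50000,
                        config = NULL), class = "porekin_trace")
  bl0 <- estimate_baseline(tr0)
  expect_equal(bl0$i0, 18.2)
  expect_equal(bl0$sigma, 0)

  # realistic trace with ~9% captured occupancy
  p <- simulate_dwells(sch, 65e-9, 20, seed = 5)
  trn <- render_trace(p, sch, trace_config(duration = 20, seed = 6))
  bln <- estimate_baseline(trn)
  expect_lt(abs(bln$i0 - 32.1) / 32.1, 0.01)
})

test_that("rectangular blockades are idealized with sample-level accuracy", {
  sch <- hsumo_scheme()
  path <- manual_path(c(0.1, 0.010, 0.05, 0.020, 0.1))
  cfg <- trace_config(noise_sigma = 0, filter_cutoff = 0, duration = 0.28)
  tr <- render_trace(path, sch, cfg)
  bl <- structure(list(i0 = 32.1, sigma = 0.1), class = "baseline_model")
  ev <- detect_events(tr, bl, deadtime = 0.001)
  cap <- ev[ev$class == "captured", ]
  expect_equal(nrow(cap), 2)
  expect_lt(max(abs(cap$duration_s - c(0.010, 0.020))), 2 * tr$dt)

  # a 0.5 ms blockade is below the 1 ms deadtime: dropped and merged
  path2 <- manual_path(c(0.1, 0.0005, 0.05, 0.020, 0.1))
  tr2 <- render_trace(path2, sch, cfg)
  ev2 <- detect_events(tr2, bl, deadtime = 0.001)
  cap2 <- ev2[ev2$class == "captured", ]
  expect_equal(nrow(cap2), 1)
  expect_lt(abs(cap2$duration_s - 0.020), 2 * tr2$dt)
  # merged released dwell spans the dropped blockade
  expect_equal(sum(ev2$class == "released"), 2)
})

test_that("event tables alternate classes and conserve trace time", {
  sch <- hsumo_scheme()
  p <- simulate_dwells(sch, 130e-9, 30, seed = 9)
  tr <- render_trace(p, sch, trace_config(duration = 30, seed = 10))
  ev <- detect_events(tr, estimate_baseline(tr))
  expect_true(all(ev$class[-1] != ev$class[-nrow(ev)]))
  expect_equal(sum(ev$duration_s), length(tr$current_pA) * tr$dt,
               tolerance = 1e-9)
  expect_true(all(diff(ev$start_s) > 0))
})

test_that("idealization recovers the generator's dwells through noise", {
  sch <- hsumo_scheme()
  # k_on * C = 8 s^-1 regime with koff ~ 66.7 s^-1
  sch2 <- kinetic_scheme("bimolecular",
                         rates = c(k_on = 1.12e8, k_off = 66.7),
                         levels = c(O_on = 32.1, O_off = 2.9))
  conc <- 8 / 1.12e8
  p <- simulate_dwells(sch2, conc, 60, seed = 31)
  tr <- render_trace(p, sch2, trace_config(duration = 60, noise_sigma = 1,
                                           seed = 32))
  ev <- detect_events(tr, estimate_baseline(tr))
  truth <- collapse_classes(p)
  n_true <- sum(truth$class == "captured" & !truth$censored)
  n_det <- sum(ev$class == "captured" & !ev$censored)
  expect_lt(abs(n_det - n_true), 3 * sqrt(n_true) + 1)

  # every true captured dwell > 5x deadtime is recovered (>= 99%)
  deadtime <- attr(ev, "deadtime")
  long_true <- truth[truth$class == "captured" & !truth$censored &
                       truth$duration_s > 5 * deadtime, ]
  det_cap <- ev[ev$class == "captured", ]
  matched <- vapply(seq_len(nrow(long_true)), function(i) {
    any(abs(det_cap$start_s - long_true$start_s[i]) < 5e-4 &
          abs(det_cap$duration_s - long_true$duration_s[i]) < 2.5e-4)
  }, logical(1))
  expect_gte(mean(matched), 0.99)
})

test_that("normalized blockade matches the reported worked examples", {
  expect_equal(normalized_blockade(32.1, 2.9), 0.909657, tolerance = 1e-6)
  expect_equal(normalized_blockade(18.2, 6.4), 0.648352, tolerance = 1e-6)
  expect_equal(normalized_blockade(7.3, 7.3), 0)
  # scale invariance
  for (c in c(0.1, 3, 1000)) {
    expect_equal(normalized_blockade(c * 32.1, c * 2.9),
                 normalized_blockade(32.1, 2.9))
  }
  expect_warning(normalized_blockade(10, 12), "enhanced")
  expect_error(normalized_blockade(0, 1), "positive")
})

test_that("the amplitude mixture resolves the published two-peak pattern", {
  withr::local_seed(77)
  n <- 1700
  m <- rbinom(n, 1, 0.28)
  a <- ifelse(m == 1, rnorm(n, 0.86, 0.03), rnorm(n, 0.65, 0.03))
  ev <- tibble::tibble(class = "captured", blockade_fraction = a,
                       duration_s = 0.1, mode = 0L, censored = FALSE,
                       start_s = seq_len(n), mean_current_pA = 0)
  fit <- fit_amplitude_mixture(ev, k = 2)
  expect_lt(abs(fit$peaks$mean[1] - 0.65), 0.01)
  expect_lt(abs(fit$peaks$mean[2] - 0.86), 0.01)
  expect_lt(abs(fit$peaks$weight[1] - 0.72), 0.03)

  # nested models: k = 2 cannot have lower likelihood
  fit1 <- fit_amplitude_mixture(ev, k = 1)
  expect_gt(fit$logL, fit1$logL)

  # unimodal data, k = 1: plain Gaussian MLE
  ev1 <- ev
  ev1$blockade_fraction <- rnorm(n, 0.65, 0.03)
  g <- fit_amplitude_mixture(ev1, k = 1)
  expect_lt(abs(g$peaks$mean[1] - 0.65), 3 * 0.03 / sqrt(n))
  expect_lt(abs(g$peaks$sd[1] - 0.03), 0.003)
})

test_that("mode assignment is maximum-posterior with documented tie-break", {
  mix <- structure(list(
    peaks = tibble::tibble(mean = c(0.65, 0.861), sd = c(0.021, 0.016),
                           weight = c(0.72, 0.28)),
    logL = 0, N = 100, k = 2), class = "amplitude_mixture")
  ev <- tibble::tibble(
    start_s = 1:5, duration_s = 0.1,
    class = c("released", "captured", "released", "captured", "captured"),
    mean_current_pA = 0,
    blockade_fraction = c(NA, 0.65, NA, 0.86, 0.65),
    mode = 0L, censored = FALSE)
  out <- assign_modes(ev, mix)
  expect_equal(out$mode[c(2, 4, 5)], c(1L, 2L, 1L))
  # released events inherit the mode of the following capture
  expect_equal(out$mode[c(1, 3)], c(1L, 2L))

  # exact posterior tie goes to the lower-index mode
  mix_tie <- structure(list(
    peaks = tibble::tibble(mean = c(0.6, 0.8), sd = c(0.05, 0.05),
                           weight = c(0.5, 0.5)),
    logL = 0, N = 100, k = 2), class = "amplitude_mixture")
  ev_tie <- ev[2, ]
  ev_tie$blockade_fraction <- 0.7
  expect_equal(assign_modes(ev_tie, mix_tie)$mode, 1L)
})

test_that("amplitude-based mode labels track the generator substates", {
  sch <- egfr_scheme()
  p <- simulate_dwells(sch, 40e-9, 250, seed = 55)
  tr <- render_trace(p, sch, trace_config(duration = 250, noise_sigma = 0.6,
                                          delta_psi = 20, seed = 56))
  ev <- detect_events(tr, estimate_baseline(tr))
  mix <- fit_amplitude_mixture(ev, k = 2)
  ev <- assign_modes(ev, mix)
  truth <- collapse_classes(p)
  tc <- truth[truth$class == "captured" & !truth$censored, ]
  dc <- ev[ev$class == "captured", ]
  # match detected captures to true dwells by start time
  idx <- findInterval(dc$start_s + 1e-4, tc$start_s)
  ok <- idx >= 1 & idx <= nrow(tc)
  agree <- mean(dc$mode[ok] == tc$mode[idx[ok]])
  expect_gte(agree, 0.95)
})
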