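#' Build a concentration series table
#'
#' Convenience constructor for the per-concentration dwell summaries that
#' feed [fit_kon()] and [fit_koff()]: one row per analyte concentration with
#' the mean released (interevent) duration tau_on and mean captured duration
#' tau_off, their standard errors and event counts.
#'
#' @param concentration_M concentrations in mol/L.
#' @param tau_on_s mean released durations, s.
#' @param tau_off_s mean captured durations, s.
#' @param tau_on_se_s,tau_off_se_s optional standard errors, s.
#' @param n_events optional event counts.
#' @param mode optional mode label (integer; NA = all events pooled).
#' @return tibble of class `concentration_series`.
#' @examples
#' # hSUMO1 dwell-time means at 65, 130 and 260 nM
#' ser <- concentration_series(c(65e-9, 130e-9, 260e-9),
#'                             tau_on_s = c(0.125, 0.069, 0.035),
#'                             tau_off_s = c(0.015, 0.016, 0.014))
#' fit_kon(ser)
#' @export
concentration_series <- function(concentration_M, tau_on_s, tau_off_s = NA_real_,
                                 tau_on_se_s = NA_real_, tau_off_se_s = NA_real_,
                                 n_events = NA_integer_, mode = NA_integer_) {
  stopifnot(all(concentration_M > 0), all(tau_on_s > 0))
  out <- tibble::tibble(concentration_M = concentration_M,
                        tau_on_s = tau_on_s, tau_off_s = tau_off_s,
                        tau_on_se_s = tau_on_se_s, tau_off_se_s = tau_off_se_s,
                        n_events = n_events, mode = mode)
  class(out) <- c("concentration_series", class(out))
  out
}

#' Association rate constant from a concentration series
#'
#' The event frequency f = 1/tau_on is proportional to the analyte
#' concentration for a bimolecular association, with slope k_on. The
#' estimator is the least-squares slope of 1/tau_on versus concentration
#' constrained through the origin; an unconstrained fit is also run and its
#' intercept reported as a lack-of-fit diagnostic. With a single
#' concentration the direct estimate k_on = 1/(C tau_on) is returned with a
#' warning.
#'
#' @param series a [concentration_series()] (or data frame with
#'   `concentration_M` and `tau_on_s`).
#' @return one-row tibble: `k_on_M1s1`, `se_M1s1`, `n_points`, plus
#'   diagnostic columns `intercept_s1`, `intercept_se_s1` from the free fit
#'   (NA with fewer than 3 points).
#' @export
fit_kon <- function(series) {
  stopifnot(is.data.frame(series))
  x <- series$concentration_M
  y <- 1 / series$tau_on_s
  if (length(x) == 1) {
    warning("single concentration: falling back to k_on = 1/(C tau_on)")
    return(tibble::tibble(k_on_M1s1 = y / x, se_M1s1 = NA_real_,
                          n_points = 1L, intercept_s1 = NA_real_,
                          intercept_se_s1 = NA_real_))
  }
  fit0 <- stats::lm(y ~ 0 + x)
  slope <- unname(stats::coef(fit0)[1])
  se <- unname(sqrt(diag(stats::vcov(fit0)))[1])
  ic <- ic_se <- NA_real_
  if (length(x) >= 3) {
    fit1 <- stats::lm(y ~ x)
    ic <- unname(stats::coef(fit1)[1])
    ic_se <- unname(sqrt(diag(stats::vcov(fit1)))[1])
  }
  tibble::tibble(k_on_M1s1 = slope, se_M1s1 = se, n_points = length(x),
                 intercept_s1 = ic, intercept_se_s1 = ic_se)
}

#' Dissociation rate constant from a concentration series
#'
#' The captured-event duration is concentration-independent for a
#' unimolecular dissociation, so k_off is estimated as the mean of 1/tau_off
#' across concentrations (the horizontal-line fit), with a standard error
#' from the scatter. A slope diagnostic (linear fit of 1/tau_off versus
#' concentration) tests the independence assumption.
#'
#' @param series a [concentration_series()] with `tau_off_s`.
#' @return one-row tibble: `k_off_s1`, `se_s1`, `n_points`, `slope_s1_M1`,
#'   `slope_se_s1_M1` (diagnostics, NA with < 3 points).
#' @export
fit_koff <- function(series) {
  stopifnot(is.data.frame(series))
  y <- 1 / series$tau_off_s
  y <- y[is.finite(y)]
  n <- length(y)
  if (n == 0) stop("no tau_off entries", call. = FALSE)
  koff <- mean(y)
  se <- if (n > 1) stats::sd(y) / sqrt(n) else NA_real_
  sl <- sl_se <- NA_real_
  if (n >= 3) {
    x <- series$concentration_M[is.finite(1 / series$tau_off_s)]
    fit <- stats::lm(y ~ x)
    sl <- unname(stats::coef(fit)[2])
    sl_se <- unname(sqrt(diag(stats::vcov(fit)))[2])
  }
  tibble::tibble(k_off_s1 = koff, se_s1 = se, n_points = n,
                 slope_s1_M1 = sl, slope_se_s1_M1 = sl_se)
}

#' Equilibrium dissociation constant K_D = k_off / k_on
#'
#' @param k_on association rate constant, M^-1 s^-1 (> 0).
#' @param k_off dissociation rate constant, s^-1.
#' @param se_k_on,se_k_off optional standard errors for first-order
#'   propagation.
#' @return one-row tibble: `kd_M`, `se_M`, `kd_nM`, `se_nM`.
#' @examples
#' compute_kd(1.12e8, 74.5)   # hSUMO1: ~665 nM
#' compute_kd(2.89e7, 1.01)   # EGFR long-lived mode: ~35 nM
#' @export
compute_kd <- function(k_on, k_off, se_k_on = NA_real_, se_k_off = NA_real_) {
  if (!is.finite(k_on) || k_on <= 0) {
    stop("k_on must be positive", call. = FALSE)
  }
  kd <- k_off / k_on
  se <- if (is.na(se_k_on) && is.na(se_k_off)) NA_real_ else {
    kd * sqrt(rel_var(se_k_on, k_on) + rel_var(se_k_off, k_off))
  }
  tibble::tibble(kd_M = kd, se_M = se, kd_nM = kd * 1e9, se_nM = se * 1e9)
}

#' Mode probabilities from labeled events
#'
#' Fraction of captured events assigned to each amplitude/duration mode, with
#' binomial standard errors. For the bimodal analyte this is the probability
#' P_i that a capture belongs to the short-lived (mode 1) or long-lived
#' (mode 2) family.
#'
#' @param events an `event_table` with mode labels (see [assign_modes()]).
#' @return tibble: `mode`, `n`, `p`, `se`.
#' @export
mode_probabilities <- function(events) {
  stopifnot(is.data.frame(events))
  cap <- events[events$class == "captured" & events$mode > 0, ]
  n_tot <- nrow(cap)
  if (n_tot == 0) stop("no mode-labeled captured events", call. = FALSE)
  out <- dplyr::count(tibble::as_tibble(cap), .data$mode, name = "n")
  out$p <- out$n / n_tot
  out$se <- sqrt(out$p * (1 - out$p) / n_tot)
  out
}

#' Per-mode interevent durations
#'
#' The mode-specific released duration tau_on-i is the released time between
#' consecutive captures of mode i: intervening captures of the other mode are
#' excluded from the clock, so that 1/tau_on-i estimates the mode-i event
#' frequency and k_on-i = 1/(tau_on-i C). Computed as the total
#' (non-censored) released time divided by the number of mode-i captures.
#'
#' @param events a mode-labeled `event_table`.
#' @return tibble: `mode`, `n_events`, `tau_on_s`, `se_s` (exponential-count
#'   approximation tau/sqrt(n)).
#' @export
mode_interevent_tau <- function(events) {
  stopifnot(is.data.frame(events))
  rel_time <- sum(events$duration_s[events$class == "released" &
                                      !events$censored])
  cap <- events[events$class == "captured" & events$mode > 0 &
                  !events$censored, ]
  if (nrow(cap) == 0) stop("no mode-labeled captured events", call. = FALSE)
  out <- dplyr::count(tibble::as_tibble(cap), .data$mode, name = "n_events")
  out$tau_on_s <- rel_time / out$n_events
  out$se_s <- out$tau_on_s / sqrt(out$n_events)
  out
}

#' Estimate analyte concentration from calibrated kinetics
#'
#' Inverts the bimolecular frequency relation: with a calibrated association
#' rate constant k_on and an observed mean interevent duration tau_on, the
#' analyte concentration is C = 1/(tau_on k_on). In multimodal data tau_on
#' must be the mode-specific interevent duration and k_on the matching
#' per-mode rate constant (this is how a biomarker is quantified in a serum
#' background from its long-lived specific captures alone).
#'
#' @param tau_on observed mean interevent duration, s (> 0).
#' @param k_on calibrated association rate constant, M^-1 s^-1 (> 0).
#' @param se_tau_on,se_k_on optional standard errors, propagated first order.
#' @return one-row tibble: `concentration_M`, `se_M`, `concentration_nM`,
#'   `se_nM`, plus the inputs.
#' @examples
#' # serum biomarker quantification from reported long-mode values
#' estimate_concentration(tau_on = 1.7, k_on = 2.9e7)
#' @export
estimate_concentration <- function(tau_on, k_on, se_tau_on = NA_real_,
                                   se_k_on = NA_real_) {
  if (!is.finite(tau_on) || tau_on <= 0 || !is.finite(k_on) || k_on <= 0) {
    stop("tau_on and k_on must be positive", call. = FALSE)
  }
  conc <- 1 / (tau_on * k_on)
  se <- if (is.na(se_tau_on) && is.na(se_k_on)) NA_real_ else {
    conc * sqrt(rel_var(se_tau_on, tau_on) + rel_var(se_k_on, k_on))
  }
  tibble::tibble(concentration_M = conc, se_M = se,
                 concentration_nM = conc * 1e9, se_nM = se * 1e9,
                 tau_on_s = tau_on, k_on_M1s1 = k_on)
}

#' Unitary conductance from current and potential
#'
#' G = I / delta_psi; with I in pA and the applied transmembrane potential in
#' mV the result is in nS.
#'
#' @param i current, pA.
#' @param delta_psi applied potential, mV (non-zero).
#' @return conductance in nS (vectorized).
#' @examples
#' conductance(32.1, 40)   # ~0.80 nS open-substate conductance
#' @export
conductance <- function(i, delta_psi) {
  if (any(delta_psi == 0)) stop("delta_psi must be non-zero", call. = FALSE)
  i / delta_psi
}

#' Summarize a concentration series into kinetic constants
#'
#' Runs [fit_kon()], [fit_koff()] and [compute_kd()] on a concentration
#' series, returning the sensor's kinetic signature in one row.
#'
#' @param series a [concentration_series()].
#' @return one-row tibble: `k_on_M1s1`, `k_on_se`, `k_off_s1`, `k_off_se`,
#'   `kd_M`, `kd_se_M`, `kd_nM`, `n_concentrations`.
#' @export
kinetics_summary <- function(series) {
  kon <- fit_kon(series)
  koff <- fit_koff(series)
  kd <- compute_kd(kon$k_on_M1s1, koff$k_off_s1, kon$se_M1s1, koff$se_s1)
  tibble::tibble(
    k_on_M1s1 = kon$k_on_M1s1, k_on_se = kon$se_M1s1,
    k_off_s1 = koff$k_off_s1, k_off_se = koff$se_s1,
    kd_M = kd$kd_M, kd_se_M = kd$se_M, kd_nM = kd$kd_nM,
    n_concentrations = nrow(series)
  )
}

# squared relative error, treating an unknown (NA) standard error as zero so
# partial uncertainty information still propagates
rel_var <- function(se, value) {
  if (is.na(se)) 0 else (se / value)^2
}
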