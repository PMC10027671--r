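#' Aggregated-Markov dwell-time model
#'
#' Internal constructor for a fitted (or fixed) rate-matrix dwell model: a
#' kinetic scheme observed only through its released/captured classes, with
#' dwell densities given by the matrix-exponential (phase-type) form.
#'
#' @keywords internal
rate_matrix_model <- function(scheme, concentration, logL = NA_real_,
                              n_params = NA_integer_, topology = scheme$preset,
                              deadtime = 0, n_dwells = NA_integer_) {
  structure(list(scheme = scheme, concentration = concentration,
                 logL = logL, n_params = n_params, topology = topology,
                 deadtime = deadtime, n_dwells = n_dwells),
            class = "rate_matrix_model")
}

#' @export
print.rate_matrix_model <- function(x, ...) {
  cat(sprintf("<rate_matrix_model> topology = %s, C = %g M, logL = %.2f\n",
              x$topology, x$concentration, x$logL))
  print(as.data.frame(x$scheme$rates), row.names = FALSE)
  invisible(x)
}

# class block Q_AA, entry distribution phi (stationary flux into the class),
# and exit vector w = -Q_AA 1 for the given class
class_blocks <- function(scheme, concentration, cls) {
  q <- generator_matrix(scheme, concentration)
  a_idx <- scheme_class_index(scheme, cls)
  f_idx <- setdiff(seq_len(nrow(q)), a_idx)
  q_aa <- q[a_idx, a_idx, drop = FALSE]
  # stationary distribution of the full chain: pi Q = 0, sum pi = 1
  n <- nrow(q)
  m <- rbind(t(q), rep(1, n))
  pi_full <- qr.solve(m, c(rep(0, n), 1))
  flux <- colSums(matrix(pi_full[f_idx], nrow = length(f_idx), ncol = length(a_idx)) *
                    q[f_idx, a_idx, drop = FALSE])
  if (sum(flux) <= 0) {
    # no flux into the class (e.g. zero concentration): fall back to uniform
    flux <- rep(1, length(a_idx))
  }
  list(q_aa = q_aa, phi = flux / sum(flux),
       w = -as.numeric(q_aa %*% rep(1, ncol(q_aa))))
}

# spectral coefficients of f(t) = sum_j c_j exp(lambda_j t)
phase_type_coef <- function(q_aa, phi, w) {
  if (nrow(q_aa) == 1) {
    return(list(lambda = unname(q_aa[1, 1]), c = unname(phi * w)))
  }
  eg <- eigen(q_aa)
  vi <- solve(eg$vectors)
  lambda <- unname(eg$values)
  cj <- as.numeric((phi %*% eg$vectors)) * as.numeric(vi %*% w)
  list(lambda = lambda, c = cj)
}

eval_phase_type <- function(coef, t) {
  out <- rep(0 + 0i, length(t))
  for (j in seq_along(coef$lambda)) {
    out <- out + coef$c[j] * exp(coef$lambda[j] * t)
  }
  pmax(Re(out), 0)
}

#' Dwell-time probability density of a rate-matrix model
#'
#' Returns the dwell-time density of the released or captured class under the
#' aggregated-Markov model: f(t) = phi' exp(Q_AA t) (-Q_AA) 1, where Q_AA is
#' the within-class block of the generator and phi the entry distribution
#' given by the stationary flux into the class. Integrates to 1 over (0,
#' Inf). With all interconversion rates zero this reduces to an exponential
#' mixture with weights proportional to the per-mode entry fluxes.
#'
#' @param model a `rate_matrix_model` (from [fit_scheme()]), or a
#'   [kinetic_scheme()] together with `concentration`.
#' @param cls `"released"` or `"captured"`.
#' @param concentration analyte concentration in mol/L (required when `model`
#'   is a bare scheme).
#' @return a vectorized density function of t (seconds).
#' @export
dwell_pdf <- function(model, cls = c("captured", "released"),
                      concentration = NULL) {
  cls <- match.arg(cls)
  bl <- resolve_blocks(model, cls, concentration)
  coef <- phase_type_coef(bl$q_aa, bl$phi, bl$w)
  function(t) eval_phase_type(coef, t)
}

#' Dwell-time cumulative distribution of a rate-matrix model
#'
#' F(t) = 1 - phi' exp(Q_AA t) 1 for the chosen class; the survivor-function
#' companion to [dwell_pdf()], usable directly in Kolmogorov-Smirnov tests.
#'
#' @inheritParams dwell_pdf
#' @return a vectorized CDF function of t.
#' @export
dwell_cdf <- function(model, cls = c("captured", "released"),
                      concentration = NULL) {
  cls <- match.arg(cls)
  bl <- resolve_blocks(model, cls, concentration)
  coef <- phase_type_coef(bl$q_aa, bl$phi, rep(1, nrow(bl$q_aa)))
  function(t) pmin(pmax(1 - eval_phase_type(coef, t), 0), 1)
}

resolve_blocks <- function(model, cls, concentration) {
  if (inherits(model, "rate_matrix_model")) {
    class_blocks(model$scheme, model$concentration, cls)
  } else if (inherits(model, "kinetic_scheme")) {
    if (is.null(concentration)) {
      stop("concentration required when passing a bare kinetic_scheme",
           call. = FALSE)
    }
    class_blocks(model, concentration, cls)
  } else {
    stop("model must be a rate_matrix_model or kinetic_scheme", call. = FALSE)
  }
}

# ---- rate-matrix maximum likelihood --------------------------------------

# spectral decomposition of the 2x2 captured block
# Q = [[-(koff1+k12), k12], [k21, -(koff2+k21)]]: eigenvalues are real for
# non-negative rates, and e^{Qt} = P1 e^{l1 t} + P2 e^{l2 t}
pt2_spectral <- function(koff1, koff2, k12, k21) {
  a <- koff1 + k12; e <- koff2 + k21
  disc <- sqrt((a - e)^2 + 4 * k12 * k21)
  if (disc < 1e-10 * max(a + e, 1)) {
    # break exact eigenvalue degeneracy with a negligible perturbation
    a <- a * (1 + 1e-8) + 1e-12
    disc <- sqrt((a - e)^2 + 4 * k12 * k21)
  }
  l1 <- (-(a + e) + disc) / 2
  l2 <- (-(a + e) - disc) / 2
  qm <- matrix(c(-a, k21, k12, -e), 2, 2)  # column-major
  p1 <- (qm - l2 * diag(2)) / (l1 - l2)
  p2 <- (l1 * diag(2) - qm) / (l1 - l2)
  list(l1 = l1, l2 = l2,
       gw1 = as.numeric(p1 %*% c(koff1, koff2)),   # [e^{Qt} w] coefficients
       gw2 = as.numeric(p2 %*% c(koff1, koff2)),
       g11 = as.numeric(p1 %*% c(1, 1)),           # [e^{Qt} 1] coefficients
       g12 = as.numeric(p2 %*% c(1, 1)))
}

# captured-class log-likelihood for the 3-state schemes. With entry-mode
# labels (1/2 per dwell) the likelihood is the joint density of (label,
# duration): phi_m [e^{Qt} w]_m / [e^{Qd} 1]_m; without labels the marginal
# phase-type density is used.
captured_loglik_2x2 <- function(t, mode, kon1, kon2, koff1, koff2, k12, k21,
                                deadtime) {
  sp <- pt2_spectral(koff1, koff2, k12, k21)
  phi <- c(kon1, kon2) / (kon1 + kon2)
  d <- deadtime
  if (is.null(mode)) {
    cf1 <- sum(phi * sp$gw1); cf2 <- sum(phi * sp$gw2)
    f <- cf1 * exp(sp$l1 * t) + cf2 * exp(sp$l2 * t)
    s_d <- sum(phi * sp$g11) * exp(sp$l1 * d) +
      sum(phi * sp$g12) * exp(sp$l2 * d)
    return(sum(log(pmax(f, 1e-300))) - length(t) * log(max(s_d, 1e-300)))
  }
  ll <- 0
  for (m in 1:2) {
    tm <- t[mode == m]
    if (length(tm) == 0) next
    g <- sp$gw1[m] * exp(sp$l1 * tm) + sp$gw2[m] * exp(sp$l2 * tm)
    s_d <- sp$g11[m] * exp(sp$l1 * d) + sp$g12[m] * exp(sp$l2 * d)
    ll <- ll + length(tm) * (log(phi[m]) - log(max(s_d, 1e-300))) +
      sum(log(pmax(g, 1e-300)))
  }
  ll
}

#' Fit a rate-matrix kinetic model to idealized events
#'
#' Maximum-likelihood estimation of the full kinetic scheme from a dwell
#' record. Released dwells are modelled as a single exponential with rate
#' (k_on1 + k_on2) C (both capture pathways compete); captured dwells by the
#' aggregated-Markov (phase-type) density of the captured class. When the
#' captured dwells carry substate/mode labels (column `mode` with values
#' 1/2, e.g. from [assign_modes()] or [collapse_classes()]), the likelihood
#' is the joint density of (entry label, duration) — under `"two_mode"` this
#' is a multinomial entry times per-mode exponentials (closed-form MLE),
#' under `"interconversion"` the entry-conditional phase-type density.
#' Without labels the marginal captured density is used; note that the
#' marginal alone cannot discriminate the two topologies (both span the same
#' order-2 mixture family), so model comparison via [compare_schemes()]
#' requires labeled dwells. All likelihood terms are deadtime-truncated.
#'
#' @param events an `event_table`, a data frame with `class`, `duration_s`
#'   (and optionally `mode`, `censored`), or a list with numeric elements
#'   `released`, `captured` (and optionally integer `captured_mode`).
#' @param topology `"two_mode"` or `"interconversion"` (or `"bimolecular"`
#'   for the 2-state scheme).
#' @param concentration analyte concentration in mol/L (> 0).
#' @param deadtime deadtime in s; default taken from the event table, else 0.
#' @param levels optional per-state current levels passed to the returned
#'   scheme (defaults to the preset's).
#' @param use_modes use mode labels if present (default TRUE).
#' @param seed seed for optimizer restarts.
#' @return a `rate_matrix_model` with fitted rates, `logL` (released +
#'   captured terms) and `n_params`.
#' @export
fit_scheme <- function(events, topology = c("two_mode", "interconversion",
                                            "bimolecular"),
                       concentration, deadtime = NULL, levels = NULL,
                       use_modes = TRUE, seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(concentration > 0)
  dw <- extract_class_dwells(events, deadtime)
  t_rel <- dw$released; t_cap <- dw$captured; d <- dw$deadtime
  mode <- if (use_modes) dw$captured_mode else NULL

  if (topology == "bimolecular") {
    kon <- 1 / (concentration * (mean(t_rel) - d))
    koff <- 1 / (mean(t_cap) - d)
    sch <- kinetic_scheme("bimolecular", rates = c(k_on = kon, k_off = koff),
                          levels = levels)
    ll <- sum(stats::dexp(t_rel - d, kon * concentration, log = TRUE)) +
      sum(stats::dexp(t_cap - d, koff, log = TRUE))
    return(rate_matrix_model(sch, concentration, ll, 2L, topology, d,
                             length(t_rel) + length(t_cap)))
  }

  free_ic <- topology == "interconversion"
  kon_tot <- 1 / (concentration * max(mean(t_rel) - d, .Machine$double.eps))
  rate_rel_ll <- function(rate_rel) {
    length(t_rel) * log(rate_rel) - rate_rel * sum(t_rel - d)
  }

  if (!free_ic && !is.null(mode)) {
    # labeled two_mode: separable closed-form MLE
    n_m <- tabulate(mode, 2)
    phi <- n_m / sum(n_m)
    koff <- vapply(1:2, function(m) 1 / (mean(t_cap[mode == m]) - d),
                   numeric(1))
    ll <- rate_rel_ll(kon_tot * concentration) +
      captured_loglik_2x2(t_cap, mode, phi[1], phi[2], koff[1], koff[2],
                          0, 0, d)
    sch <- kinetic_scheme("two_mode",
                          rates = c(k_on1 = kon_tot * phi[1],
                                    k_on2 = kon_tot * phi[2],
                                    k_off1 = koff[1], k_off2 = koff[2]),
                          levels = levels)
    return(rate_matrix_model(sch, concentration, ll, 4L, topology, d,
                             length(t_rel) + length(t_cap)))
  }

  nll <- function(theta) {
    r <- exp(theta)
    if (any(!is.finite(r)) || any(r > 1e15)) return(1e10)
    kon1 <- r[1]; kon2 <- r[2]; koff1 <- r[3]; koff2 <- r[4]
    k12 <- if (free_ic) r[5] else 0
    k21 <- if (free_ic) r[6] else 0
    val <- -(rate_rel_ll((kon1 + kon2) * concentration) +
               captured_loglik_2x2(t_cap, mode, kon1, kon2, koff1, koff2,
                                   k12, k21, d))
    if (!is.finite(val)) 1e10 else val
  }

  # initialize from the labeled closed form or a mixture fit
  if (!is.null(mode)) {
    n_m <- pmax(tabulate(mode, 2), 1)
    phi <- n_m / sum(n_m)
    init <- c(kon1 = kon_tot * phi[1], kon2 = kon_tot * phi[2],
              koff1 = 1 / max(mean(t_cap[mode == 1]) - d, 1e-6),
              koff2 = 1 / max(mean(t_cap[mode == 2]) - d, 1e-6))
  } else {
    mix <- tryCatch(fit_exp_mixture(t_cap, k = 2, deadtime = d, seed = seed,
                                    n_restarts = 2),
                    error = function(e) NULL)
    if (!is.null(mix)) {
      w1 <- mix$components$weight[1]
      init <- c(kon1 = kon_tot * w1, kon2 = kon_tot * (1 - w1),
                koff1 = 1 / mix$components$tau_s[1],
                koff2 = 1 / mix$components$tau_s[2])
    } else {
      koff0 <- 1 / mean(t_cap)
      init <- c(kon1 = kon_tot * 0.6, kon2 = kon_tot * 0.4,
                koff1 = koff0 * 3, koff2 = koff0 / 3)
    }
  }
  if (free_ic) init <- c(init, k_12 = 0.05 * init[["koff1"]],
                         k_21 = 0.05 * init[["koff1"]])
  fit <- stats::optim(log(init), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-10))
  r <- exp(fit$par)
  rates <- c(k_on1 = r[[1]], k_on2 = r[[2]], k_off1 = r[[3]], k_off2 = r[[4]])
  if (free_ic) rates <- c(rates, k_12 = r[[5]], k_21 = r[[6]])
  sch <- kinetic_scheme(if (free_ic) "interconversion" else "two_mode",
                        rates = rates, levels = levels)
  rate_matrix_model(sch, concentration, -fit$value,
                    n_params = if (free_ic) 6L else 4L,
                    topology = topology, deadtime = d,
                    n_dwells = length(t_rel) + length(t_cap))
}

extract_class_dwells <- function(events, deadtime = NULL) {
  if (is.list(events) && !is.data.frame(events) &&
      all(c("released", "captured") %in% names(events))) {
    d <- deadtime %||% 0
    keep <- events$captured >= d
    cm <- events$captured_mode
    if (!is.null(cm)) {
      cm <- cm[keep]
      if (!all(cm %in% 1:2)) cm <- NULL
    }
    return(list(released = events$released[events$released >= d],
                captured = events$captured[keep],
                captured_mode = cm, deadtime = d))
  }
  stopifnot(is.data.frame(events))
  d <- deadtime %||% attr(events, "deadtime") %||% 0
  cap <- dwell_sample(events, "captured", deadtime = d)$durations
  cm <- NULL
  if (!is.null(events$mode)) {
    keep <- events$class == "captured"
    if (!is.null(events$censored)) keep <- keep & !events$censored
    sub <- events[keep, ]
    sub <- sub[sub$duration_s >= d, ]
    if (nrow(sub) == length(cap) && all(sub$mode %in% 1:2)) cm <- sub$mode
  }
  list(released = dwell_sample(events, "released", deadtime = d)$durations,
       captured = cap, captured_mode = cm, deadtime = d)
}

#' Likelihood-ratio comparison of nested rate-matrix models
#'
#' Standard LLR decision between two nested fits on the same dwell record:
#' the richer model is superior only when 2 (logL2 - logL1) strictly exceeds
#' the chi-squared quantile at the given confidence with df equal to the
#' parameter-count difference.
#'
#' @param m1 the simpler `rate_matrix_model` (e.g. two_mode).
#' @param m2 the richer nested model (e.g. interconversion).
#' @param confidence confidence level (default 0.95).
#' @return an `llr_decision` with `superior`, `llr`, `critical`, `df`.
#' @export
compare_schemes <- function(m1, m2, confidence = 0.95) {
  stopifnot(inherits(m1, "rate_matrix_model"),
            inherits(m2, "rate_matrix_model"))
  df <- m2$n_params - m1$n_params
  if (df < 0) {
    stop("models are not nested in the given order (m1 must be the simpler)",
         call. = FALSE)
  }
  llr <- 2 * (m2$logL - m1$logL)
  crit <- if (df == 0) 0 else stats::qchisq(confidence, df = df)
  structure(list(chosen_k = if (llr > crit) 2L else 1L,
                 comparisons = tibble::tibble(
                   k_null = 1L, k_alt = 2L, llr = llr, critical = crit,
                   superior = llr > crit),
                 confidence = confidence,
                 superior = llr > crit, llr = llr, critical = crit, df = df),
            class = "llr_decision")
}
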