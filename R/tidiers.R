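#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an exponential-mixture dwell fit
#'
#' @param x an `exp_mixture_fit`.
#' @param ... unused.
#' @return tibble with one row per component: `component`, `weight`,
#'   `tau_s`, `se_weight`, `se_tau_s`, `rate_s1`.
#' @method tidy exp_mixture_fit
#' @export
tidy.exp_mixture_fit <- function(x, ...) {
  dplyr::mutate(x$components,
                component = dplyr::row_number(),
                rate_s1 = 1 / .data$tau_s,
                .before = 1)
}

#' @rdname tidy.exp_mixture_fit
#' @return for `glance`: one row with `k`, `logL`, `AIC`, `N`, `deadtime_s`.
#' @method glance exp_mixture_fit
#' @export
glance.exp_mixture_fit <- function(x, ...) {
  tibble::tibble(k = x$k, logL = x$logL,
                 AIC = -2 * x$logL + 2 * (2 * x$k - 1),
                 N = x$N, deadtime_s = x$deadtime)
}

#' Tidy a blockade-amplitude mixture
#'
#' @param x an `amplitude_mixture`.
#' @param ... unused.
#' @return tibble: `mode`, `mean`, `sd`, `weight`.
#' @method tidy amplitude_mixture
#' @export
tidy.amplitude_mixture <- function(x, ...) {
  dplyr::mutate(x$peaks, mode = dplyr::row_number(), .before = 1)
}

#' @rdname tidy.amplitude_mixture
#' @method glance amplitude_mixture
#' @export
glance.amplitude_mixture <- function(x, ...) {
  tibble::tibble(k = x$k, logL = x$logL, N = x$N)
}

#' Tidy a fitted rate-matrix model
#'
#' @param x a `rate_matrix_model`.
#' @param ... unused.
#' @return tibble of fitted rate constants: `term`, `estimate`, `units`.
#' @method tidy rate_matrix_model
#' @export
tidy.rate_matrix_model <- function(x, ...) {
  r <- x$scheme$rates
  tibble::tibble(
    term = paste0(r$from, "->", r$to),
    estimate = r$rate,
    units = ifelse(r$concentration_scaled, "M^-1 s^-1", "s^-1")
  )
}

#' @rdname tidy.rate_matrix_model
#' @method glance rate_matrix_model
#' @export
glance.rate_matrix_model <- function(x, ...) {
  tibble::tibble(topology = x$topology, logL = x$logL,
                 n_params = x$n_params, n_dwells = x$n_dwells,
                 concentration_M = x$concentration)
}

#' Tidy an LLR model-selection decision
#'
#' @param x an `llr_decision`.
#' @param ... unused.
#' @return the pairwise comparison tibble (`k_null`, `k_alt`, `llr`,
#'   `critical`, `superior`).
#' @method tidy llr_decision
#' @export
tidy.llr_decision <- function(x, ...) x$comparisons

#' @rdname tidy.llr_decision
#' @method glance llr_decision
#' @export
glance.llr_decision <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k, confidence = x$confidence)
}

#' Tidy a noise-model fit
#'
#' @param x a `noise_fit`.
#' @param ... unused.
#' @return one-row tibble: `s_white_pA2_Hz`, `a_flicker`, `alpha`,
#'   `flicker_share`, `classification`.
#' @method tidy noise_fit
#' @export
tidy.noise_fit <- function(x, ...) {
  tibble::tibble(s_white_pA2_Hz = x$s_white, a_flicker = x$a_flicker,
                 alpha = x$alpha, flicker_share = x$flicker_share,
                 classification = x$classification)
}
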