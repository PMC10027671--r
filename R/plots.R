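#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a current trace
#'
#' Current versus time; traces longer than `max_points` samples are
#' downsampled by min/max decimation so blockades remain visible.
#'
#' @param object a `porekin_trace`.
#' @param max_points maximum points drawn.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot porekin_trace
#' @export
autoplot.porekin_trace <- function(object, max_points = 2e4, ...) {
  df <- as_tibble.porekin_trace(object)
  n <- nrow(df)
  if (n > max_points) {
    grp <- ceiling(seq_len(n) / ceiling(n / (max_points / 2)))
    df <- dplyr::group_by(df, grp) |>
      dplyr::summarise(time_s = mean(.data$time_s),
                       lo = min(.data$current_pA),
                       hi = max(.data$current_pA), .groups = "drop")
    return(ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s)) +
             ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo,
                                               ymax = .data$hi),
                                  fill = "firebrick", alpha = 0.8) +
             ggplot2::labs(x = "time (s)", y = "current (pA)") +
             ggplot2::theme_minimal())
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$current_pA)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "current (pA)") +
    ggplot2::theme_minimal()
}

#' Plot a log-binned dwell-time histogram with a mixture fit overlay
#'
#' Square-root-ordinate semilogarithmic dwell histogram; an exponential
#' component appears as a peak at its time constant. If a fit is supplied its
#' truncated-mixture density is drawn on the same transformed scale.
#'
#' @param object an `exp_mixture_fit`.
#' @param dwells the [dwell_sample()] (or numeric durations) the fit used.
#' @param bins_per_decade histogram resolution.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot exp_mixture_fit
#' @export
autoplot.exp_mixture_fit <- function(object, dwells, bins_per_decade = 10,
                                     ...) {
  dw <- as_dwell_sample(dwells, object$deadtime)
  h <- log_binned_histogram(dw, bins_per_decade)
  n <- length(dw$durations)
  width <- log(10) / bins_per_decade
  # expected counts per log bin under the fitted truncated mixture
  grid <- exp(seq(log(min(h$bin_lo_s)), log(max(h$bin_hi_s)),
                  length.out = 200))
  dens <- exp(exp_mixture_logdensity(grid, object$components$weight,
                                     object$components$tau_s,
                                     object$deadtime))
  curve <- tibble::tibble(t = grid, y = sqrt(n * width * grid * dens))
  ggplot2::ggplot(h, ggplot2::aes(.data$bin_mid_s, .data$sqrt_count)) +
    ggplot2::geom_col(width = 0.08, fill = "grey70") +
    ggplot2::geom_line(data = curve, ggplot2::aes(.data$t, .data$y),
                       colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dwell time (s)", y = expression(sqrt(count))) +
    ggplot2::theme_minimal()
}

#' Plot a blockade-amplitude histogram with mixture components
#'
#' @param object an `amplitude_mixture`.
#' @param events the event table the mixture was fitted to.
#' @param binwidth histogram bin width on the blockade-fraction axis.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot amplitude_mixture
#' @export
autoplot.amplitude_mixture <- function(object, events, binwidth = 0.01, ...) {
  a <- amplitude_vector(events)
  grid <- seq(max(0, min(a) - 0.05), min(1, max(a) + 0.05), length.out = 300)
  comp <- purrr::map_dfr(seq_len(nrow(object$peaks)), function(i) {
    p <- object$peaks[i, ]
    tibble::tibble(mode = factor(i), x = grid,
                   y = length(a) * binwidth * p$weight *
                     stats::dnorm(grid, p$mean, p$sd))
  })
  ggplot2::ggplot(tibble::tibble(a = a), ggplot2::aes(.data$a)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey70") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(.data$x, .data$y, colour = .data$mode)) +
    ggplot2::labs(x = expression(A / I[0]), y = "events") +
    ggplot2::theme_minimal()
}

#' Plot a power spectral density with optional noise-model overlay
#'
#' @param object a `psd_spectrum`.
#' @param fit optional `noise_fit` whose model curve is overlaid.
#' @param ... unused.
#' @return a ggplot (log-log axes).
#' @method autoplot psd_spectrum
#' @export
autoplot.psd_spectrum <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$frequency_Hz, .data$psd_pA2_Hz)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)",
                  y = expression(S(f) ~ (pA^2 / Hz))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- exp(seq(log(min(object$frequency_Hz)),
                    log(max(object$frequency_Hz)), length.out = 200))
    mod <- tibble::tibble(f = grid,
                          s = fit$s_white + fit$a_flicker / grid^fit$alpha)
    p <- p + ggplot2::geom_line(data = mod, ggplot2::aes(.data$f, .data$s),
                                colour = "black", linetype = 2)
  }
  p
}

#' Plot event frequency versus concentration with the through-origin fit
#'
#' @param object a `concentration_series`.
#' @param ... unused.
#' @return a ggplot of 1/tau_on against concentration (nM).
#' @method autoplot concentration_series
#' @export
autoplot.concentration_series <- function(object, ...) {
  kon <- fit_kon(object)
  df <- tibble::tibble(conc_nM = object$concentration_M * 1e9,
                       f = 1 / object$tau_on_s)
  line <- tibble::tibble(conc_nM = c(0, max(df$conc_nM)),
                         f = kon$k_on_M1s1 * c(0, max(df$conc_nM)) * 1e-9)
  ggplot2::ggplot(df, ggplot2::aes(.data$conc_nM, .data$f)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "red") +
    ggplot2::labs(x = "[analyte] (nM)", y = expression(1 / tau[on] ~ (s^-1))) +
    ggplot2::theme_minimal()
}
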