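#' Acquisition and rendering configuration for synthetic traces
#'
#' Collects the acquisition parameters used to render a simulated state path
#' into a single-channel current trace: sampling rate, low-pass Bessel filter,
#' white instrument noise, and optional 1/f^alpha flicker noise emulating the
#' low-frequency fluctuations seen with serum-containing (biofluid) buffers.
#'
#' @param sampling_rate sampling frequency in Hz (default 50 kHz).
#' @param filter_cutoff -3 dB cutoff of the digital 8-pole Bessel low-pass
#'   filter in Hz (default 3 kHz); `0` disables filtering. Must satisfy
#'   `sampling_rate > 2 * filter_cutoff`.
#' @param filter_poles filter order (default 8).
#' @param noise_sigma white Gaussian instrument noise s.d. in pA.
#' @param flicker_amplitude one-sided flicker PSD amplitude at 1 Hz in
#'   pA^2 Hz^(alpha-1); `0` turns flicker noise off.
#' @param flicker_alpha flicker spectral exponent (default 1).
#' @param duration trace duration in s (used when simulating end-to-end).
#' @param delta_psi applied transmembrane potential in mV (metadata).
#' @param concentration analyte concentration in mol/L (metadata).
#' @param seed integer seed for noise generation.
#' @return A list of class `trace_config`.
#' @export
trace_config <- function(sampling_rate = 50000, filter_cutoff = 3000,
                         filter_poles = 8, noise_sigma = 1,
                         flicker_amplitude = 0, flicker_alpha = 1,
                         duration = 10, delta_psi = 40,
                         concentration = NA_real_, seed = 1L) {
  stopifnot(sampling_rate > 0, filter_cutoff >= 0, filter_poles >= 1,
            noise_sigma >= 0, flicker_amplitude >= 0, flicker_alpha > 0,
            duration > 0)
  if (filter_cutoff > 0 && sampling_rate <= 2 * filter_cutoff) {
    stop("Nyquist violation: sampling_rate must exceed 2 * filter_cutoff",
         call. = FALSE)
  }
  structure(list(sampling_rate = sampling_rate, filter_cutoff = filter_cutoff,
                 filter_poles = filter_poles, noise_sigma = noise_sigma,
                 flicker_amplitude = flicker_amplitude,
                 flicker_alpha = flicker_alpha, duration = duration,
                 delta_psi = delta_psi, concentration = concentration,
                 seed = as.integer(seed)),
            class = "trace_config")
}

#' Gillespie simulation of a gating state path
#'
#' Simulates a realization of the scheme's continuous-time Markov chain by the
#' Gillespie (stochastic simulation) algorithm. The chain starts in the
#' released state; the dwell in each state is exponential with rate equal to
#' the total outgoing rate (association pathways multiplied by the analyte
#' concentration), and the successor state is drawn with probability
#' proportional to its rate. The final dwell is truncated at `duration` and
#' flagged as right-censored.
#'
#' @param scheme a [kinetic_scheme()].
#' @param concentration analyte concentration in mol/L.
#' @param duration total simulated time in s.
#' @param seed integer seed; the same seed gives a bit-identical path.
#' @return A tibble of class `state_path` with one row per dwell: `state`,
#'   `class` (released/captured), `start_s`, `duration_s`, `censored`.
#'   Attributes: `scheme`, `concentration`, `duration`, `seed`.
#' @examples
#' sch <- kinetic_scheme("bimolecular",
#'                       rates = c(k_on = 1.12e8, k_off = 74.5))
#' path <- simulate_dwells(sch, concentration = 260e-9, duration = 5, seed = 7)
#' head(path)
#' @export
simulate_dwells <- function(scheme, concentration, duration, seed = 1L) {
  stopifnot(inherits(scheme, "kinetic_scheme"), duration > 0,
            concentration >= 0)
  q <- generator_matrix(scheme, concentration)
  if (any(!is.finite(q))) stop("non-finite rate in generator", call. = FALSE)
  n_states <- nrow(q)
  exit_rate <- -diag(q)
  # per-state successor distributions
  succ <- vector("list", n_states)
  for (s in seq_len(n_states)) {
    if (exit_rate[s] > 0) {
      pr <- q[s, ]
      pr[s] <- 0
      succ[[s]] <- pr / exit_rate[s]
    }
  }
  start_state <- scheme_class_index(scheme, "released")[1]

  withr::local_seed(as.integer(seed))
  cap <- 4096L
  st <- integer(cap); dur <- numeric(cap)
  n <- 0L; t <- 0; cur <- start_state
  censored_last <- FALSE
  repeat {
    if (exit_rate[cur] <= 0) {
      dw <- duration - t
      censored_last <- TRUE
    } else {
      dw <- stats::rexp(1L, exit_rate[cur])
      if (t + dw >= duration) {
        dw <- duration - t
        censored_last <- TRUE
      }
    }
    n <- n + 1L
    if (n > cap) {
      cap <- cap * 2L
      length(st) <- cap; length(dur) <- cap
    }
    st[n] <- cur; dur[n] <- dw; t <- t + dw
    if (censored_last) break
    cur <- sample.int(n_states, 1L, prob = succ[[cur]])
  }
  st <- st[seq_len(n)]; dur <- dur[seq_len(n)]
  path <- tibble::tibble(
    state = scheme$states$name[st],
    class = scheme$states$class[st],
    start_s = cumsum(c(0, dur[-n])),
    duration_s = dur,
    censored = c(rep(FALSE, n - 1L), TRUE)
  )
  attr(path, "scheme") <- scheme
  attr(path, "concentration") <- concentration
  attr(path, "duration") <- duration
  attr(path, "seed") <- as.integer(seed)
  class(path) <- c("state_path", class(path))
  path
}

#' Collapse a state path to aggregated class dwells
#'
#' Merges consecutive dwells sharing the same class (released/captured) into
#' single aggregated dwells — the durations an idealized recording actually
#' resolves, since captured substates that interconvert without visiting the
#' released state appear as one uninterrupted blockade when amplitudes are
#' ignored.
#'
#' @param path a `state_path` from [simulate_dwells()].
#' @return A tibble with `class`, `entry_state` (first substate of the run),
#'   `mode` (index of the entry substate among the captured states; 0 for
#'   released), `start_s`, `duration_s`, `censored` (TRUE if the aggregated
#'   dwell contains the censored tail dwell).
#' @export
collapse_classes <- function(path) {
  r <- rle(path$class)
  grp <- rep(seq_along(r$lengths), r$lengths)
  entry <- as.character(tapply(path$state, grp, `[`, 1L))
  scheme <- attr(path, "scheme")
  mode <- rep(0L, length(entry))
  if (!is.null(scheme)) {
    cap_states <- scheme$states$name[scheme$states$class == "captured"]
    m <- match(entry, cap_states)
    mode[!is.na(m)] <- m[!is.na(m)]
  }
  tibble::tibble(
    class = r$values,
    entry_state = entry,
    mode = mode,
    start_s = as.numeric(tapply(path$start_s, grp, `[`, 1L)),
    duration_s = as.numeric(tapply(path$duration_s, grp, sum)),
    censored = as.logical(tapply(path$censored, grp, any))
  )
}

#' Render a state path into a noisy, filtered current trace
#'
#' Forward model of a single-channel recording: the path is converted to a
#' piecewise-constant current at the per-state levels, white Gaussian noise
#' and (optionally) spectrally shaped 1/f^alpha flicker noise are added, the
#' result is passed through a digital 8-pole Bessel low-pass filter, and
#' sampled uniformly at the configured rate.
#'
#' @param path a `state_path` from [simulate_dwells()].
#' @param scheme the [kinetic_scheme()] that produced the path (for levels).
#' @param config a [trace_config()]; its `seed` drives the noise.
#' @return An object of class `porekin_trace`: list with `current_pA`
#'   (numeric vector), `dt` (s) and `config`.
#' @export
render_trace <- function(path, scheme, config) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(config, "trace_config"))
  fs <- config$sampling_rate
  total <- sum(path$duration_s)
  if (total < 1 / fs) stop("path shorter than one sample", call. = FALSE)
  n <- floor(total * fs)
  t_sample <- (seq_len(n) - 0.5) / fs
  # state at each sample time
  edges <- cumsum(path$duration_s)
  idx <- findInterval(t_sample, c(0, edges), rightmost.closed = TRUE)
  idx[idx > nrow(path)] <- nrow(path)
  levels <- scheme$states$level_pA[match(path$state, scheme$states$name)]
  x <- levels[idx]

  withr::local_seed(as.integer(config$seed))
  if (config$noise_sigma > 0) {
    x <- x + stats::rnorm(n, sd = config$noise_sigma)
  }
  if (config$flicker_amplitude > 0) {
    x <- x + synth_flicker(n, fs, config$flicker_amplitude,
                           config$flicker_alpha)
  }
  if (config$filter_cutoff > 0) {
    x <- bessel_lowpass(x, fs, config$filter_cutoff, config$filter_poles)
  }
  structure(list(current_pA = x, dt = 1 / fs, config = config),
            class = "porekin_trace")
}

#' @export
print.porekin_trace <- function(x, ...) {
  cat(sprintf("<porekin_trace> %d samples, %.3f s at %g kHz\n",
              length(x$current_pA), length(x$current_pA) * x$dt,
              1e-3 / x$dt))
  invisible(x)
}

#' Convert a trace to a tibble of (time, current)
#'
#' @param x a `porekin_trace`.
#' @param ... unused.
#' @return tibble with `time_s`, `current_pA`.
#' @method as_tibble porekin_trace
#' @export
as_tibble.porekin_trace <- function(x, ...) {
  tibble::tibble(time_s = (seq_along(x$current_pA) - 0.5) * x$dt,
                 current_pA = x$current_pA)
}

# ---- 1/f^alpha noise synthesis ------------------------------------------

# Gaussian noise with one-sided PSD S(f) = amplitude / f^alpha, synthesized by
# inverse-FFT spectral shaping with independent random phases. DC is zeroed.
synth_flicker <- function(n, fs, amplitude, alpha) {
  m <- n %/% 2
  f <- (1:m) * fs / n
  s <- amplitude / f^alpha            # one-sided PSD target, pA^2/Hz
  mag <- sqrt(s * fs * n / 4)         # E|X_k|^2 = S fs n / 2
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) * mag
  if (n %% 2 == 0) z[m] <- complex(real = sqrt(2) * Re(z[m]), imaginary = 0)
  spec <- complex(length.out = n)
  spec[2:(m + 1)] <- z
  spec[n:(n - m + 2)] <- Conj(z[seq_len(m - 1)])
  Re(stats::fft(spec, inverse = TRUE)) / n
}

# ---- digital Bessel low-pass ---------------------------------------------

# Reverse Bessel polynomial theta_n(s) coefficients (ascending powers), by the
# recurrence theta_n = (2n-1) theta_{n-1} + s^2 theta_{n-2}.
reverse_bessel_poly <- function(n) {
  th0 <- 1
  th1 <- c(1, 1)
  if (n == 0) return(th0)
  if (n == 1) return(th1)
  for (k in 2:n) {
    a <- (2 * k - 1) * c(th1, 0)
    b <- c(0, 0, th0)
    length(b) <- length(a)
    thk <- a + ifelse(is.na(b), 0, b)
    th0 <- th1
    th1 <- thk
  }
  th1
}

# Analog Bessel low-pass prototype poles, scaled so the -3 dB point is at
# 1 rad/s. Cached per order.
bessel_prototype <- local({
  cache <- list()
  function(order) {
    key <- as.character(order)
    if (!is.null(cache[[key]])) return(cache[[key]])
    coef <- reverse_bessel_poly(order)    # ascending powers of s
    poles <- polyroot(coef)
    gain <- abs(prod(-poles))             # = theta_n(0)
    hmag2 <- function(w) {
      vapply(w, function(wi) {
        (gain / abs(prod(complex(imaginary = wi) - poles)))^2
      }, numeric(1))
    }
    w3 <- stats::uniroot(function(w) hmag2(w) - 0.5, c(1e-3, 10 * order),
                         tol = 1e-12)$root
    out <- list(poles = poles / w3, order = order)
    cache[[key]] <<- out
    out
  }
})

# Digital Bessel low-pass via bilinear transform of the analog prototype with
# frequency pre-warping; returns filter coefficients b (num), a (den).
bessel_digital_coef <- function(fs, fc, order = 8) {
  proto <- bessel_prototype(order)
  wa <- 2 * fs * tan(pi * fc / fs)       # pre-warped analog cutoff, rad/s
  p <- proto$poles * wa
  zp <- (2 * fs + p) / (2 * fs - p)      # bilinear-transformed poles
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)               # unity gain at DC
  list(b = b, a = a)
}

# monic polynomial coefficients (descending powers) from roots
poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
  coef
}

# Apply the digital 8-pole Bessel low-pass. The input is padded at both ends
# with its edge values to suppress filter start-up transients.
bessel_lowpass <- function(x, fs, fc, order = 8) {
  co <- bessel_digital_coef(fs, fc, order)
  pad <- min(length(x), ceiling(4 * fs / fc))
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  y <- signal::filter(co$b, co$a, xp)
  as.numeric(y)[pad + seq_along(x)]
}

#' 10-90% rise time of the implemented Bessel filter
#'
#' Measures the step response of the digital filter at the given sampling rate
#' and cutoff. For a Bessel (near-Gaussian) response the rise time is
#' approximately `0.3321 / filter_cutoff`; the default event-detection
#' deadtime is set to this value because shorter blockades are attenuated
#' below threshold.
#'
#' @param fs sampling rate, Hz.
#' @param fc filter cutoff, Hz.
#' @param order filter order.
#' @return rise time in seconds.
#' @export
filter_rise_time <- function(fs, fc, order = 8) {
  n <- max(256, ceiling(20 * fs / fc))
  step <- c(rep(0, n), rep(1, n))
  y <- bessel_lowpass(step, fs, fc, order)
  t10 <- which(y >= 0.1)[1]
  t90 <- which(y >= 0.9)[1]
  # linear interpolation between samples
  f10 <- t10 - 1 + (0.1 - y[t10 - 1]) / (y[t10] - y[t10 - 1])
  f90 <- t90 - 1 + (0.9 - y[t90 - 1]) / (y[t90] - y[t90 - 1])
  (f90 - f10) / fs
}
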