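#' Estimate the open-substate baseline of a trace
#'
#' Fits the all-points current histogram and returns the mean and s.d. of the
#' dominant highest-current Gaussian peak, i.e. the open-substate current
#' `I_0` of the analyte-released level. Blockades occupy lower-current peaks
#' and are excluded by taking the highest-mean component.
#'
#' @param trace a `porekin_trace`.
#' @param max_components maximum number of Gaussian components tried for the
#'   all-points histogram (default 3).
#' @return list of class `baseline_model` with `i0` (pA) and `sigma` (pA).
#' @export
estimate_baseline <- function(trace, max_components = 3) {
  stopifnot(inherits(trace, "porekin_trace"))
  x <- trace$current_pA
  if (length(x) * trace$dt < 1) {
    stop("trace must contain at least 1 s of data", call. = FALSE)
  }
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    # noiseless constant trace: the histogram collapses to a single bin
    return(structure(list(i0 = mean(x), sigma = 0), class = "baseline_model"))
  }
  # subsample for speed; the baseline occupies most points
  if (length(x) > 2e5) {
    x <- x[seq(1, length(x), length.out = 2e5)]
  }
  fit <- tryCatch(
    mclust::densityMclust(x, G = seq_len(max_components), modelNames = "V",
                          verbose = FALSE, plot = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    stop("baseline estimation failed: no resolvable current peak", call. = FALSE)
  }
  top <- which.max(fit$parameters$mean)
  structure(list(i0 = unname(fit$parameters$mean[top]),
                 sigma = sqrt(unname(fit$parameters$variance$sigmasq[
                   min(top, length(fit$parameters$variance$sigmasq))]))),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model> I0 = %.2f pA, sigma = %.2f pA\n",
              x$i0, x$sigma))
  invisible(x)
}

#' Idealize a current trace into alternating released/captured events
#'
#' Half-amplitude threshold idealization: a captured event opens when the
#' current crosses below the detection threshold and closes when it
#' re-crosses. By default the threshold is half the open-substate current
#' (`threshold_fraction = 0.5` of the span from `i0` down to 0); when the
#' deepest expected blockade level is supplied the threshold is placed at
#' `i0 - threshold_fraction * (i0 - deepest_level)`. Events shorter than the
#' deadtime are discarded and their time merged into the flanking event of
#' the other class (both for brief blockades and brief reopenings); the
#' deadtime defaults to the filter rise time `0.3321 / filter_cutoff`.
#' Optionally, captured events shorter than `spike_cutoff` are excluded after
#' idealization to remove brief nonspecific spikes such as those produced by
#' serum constituents (their time is merged into the flanking released
#' events).
#'
#' @param trace a `porekin_trace`.
#' @param baseline a `baseline_model` from [estimate_baseline()].
#' @param threshold_fraction fractional depth of the detection threshold in
#'   (0, 1); default 0.5 (half-amplitude).
#' @param deadtime minimum resolvable event duration in s; default the filter
#'   rise time, or one sample when the trace is unfiltered.
#' @param deepest_level current level (pA) of the deepest expected blockade;
#'   default 0.
#' @param spike_cutoff minimum captured-event duration in s retained as a
#'   genuine capture (`0` = keep all; used for biofluid-mode analysis).
#' @return A tibble of class `event_table` with columns `start_s`,
#'   `duration_s`, `class`, `mean_current_pA`, `blockade_fraction`, `mode`,
#'   `censored`. Attributes: `i0`, `deadtime`, `dt`, `low_confidence`.
#' @export
detect_events <- function(trace, baseline, threshold_fraction = 0.5,
                          deadtime = NULL, deepest_level = 0,
                          spike_cutoff = 0) {
  stopifnot(inherits(trace, "porekin_trace"),
            inherits(baseline, "baseline_model"),
            threshold_fraction > 0, threshold_fraction < 1)
  fs <- 1 / trace$dt
  cfg <- trace$config
  if (is.null(deadtime)) {
    deadtime <- if (!is.null(cfg) && cfg$filter_cutoff > 0) {
      0.3321 / cfg$filter_cutoff
    } else {
      1 / fs
    }
  }
  if (deadtime < 1 / fs) {
    stop("deadtime must be at least one sample", call. = FALSE)
  }
  i0 <- baseline$i0
  threshold <- i0 - threshold_fraction * (i0 - deepest_level)
  low_confidence <- FALSE
  if (baseline$sigma >= (i0 - deepest_level) / 2) {
    warning("baseline noise is comparable to the level separation; ",
            "idealization flagged low-confidence")
    low_confidence <- TRUE
  }
  x <- trace$current_pA
  below <- x < threshold

  r <- rle(below)
  dead_n <- round(deadtime * fs)
  # drop sub-deadtime captured runs first, then sub-deadtime released runs,
  # merging their samples into the flanking runs of the other class
  r <- drop_short_runs(r, dead_n, value = TRUE)
  r <- drop_short_runs(r, dead_n, value = FALSE)
  if (spike_cutoff > 0) {
    r <- drop_short_runs(r, round(spike_cutoff * fs), value = TRUE)
  }

  n_ev <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  rise_n <- if (!is.null(cfg) && cfg$filter_cutoff > 0) {
    ceiling(0.3321 / cfg$filter_cutoff * fs)
  } else 0L
  mean_cur <- vapply(seq_len(n_ev), function(i) {
    s <- starts[i]; e <- ends[i]
    s2 <- min(s + rise_n, e)   # skip filter-rise samples where possible
    mean(x[s2:e])
  }, numeric(1))

  cls <- ifelse(r$values, "captured", "released")
  bf <- rep(NA_real_, n_ev)
  if (any(r$values)) {
    bf[r$values] <- normalized_blockade(i0, mean_cur[r$values])
  }
  events <- tibble::tibble(
    start_s = (starts - 1L) / fs,
    duration_s = r$lengths / fs,
    class = cls,
    mean_current_pA = mean_cur,
    blockade_fraction = bf,
    mode = 0L,
    censored = seq_len(n_ev) %in% c(1L, n_ev)
  )
  attr(events, "i0") <- i0
  attr(events, "deadtime") <- deadtime
  attr(events, "dt") <- trace$dt
  attr(events, "low_confidence") <- low_confidence
  class(events) <- c("event_table", class(events))
  events
}

# merge runs of `value` shorter than min_len into their neighbours
drop_short_runs <- function(r, min_len, value) {
  repeat {
    short <- which(r$values == value & r$lengths < min_len)
    if (length(short) == 0 || length(r$lengths) == 1) break
    i <- short[1]
    if (i == 1) {
      r$lengths[2] <- r$lengths[2] + r$lengths[1]
      keep <- -1L
    } else if (i == length(r$lengths)) {
      r$lengths[i - 1] <- r$lengths[i - 1] + r$lengths[i]
      keep <- -i
    } else {
      r$lengths[i - 1] <- r$lengths[i - 1] + r$lengths[i] + r$lengths[i + 1]
      keep <- -c(i, i + 1L)
    }
    r$lengths <- r$lengths[keep]
    r$values <- r$values[keep]
    # merging can create adjacent equal-valued runs; re-consolidate
    rr <- rle(inverse.rle(list(lengths = rep(1L, length(r$values)),
                               values = r$values)))
    if (any(rr$lengths > 1)) {
      grp <- rep(seq_along(rr$lengths), rr$lengths)
      r <- list(lengths = as.integer(tapply(r$lengths, grp, sum)),
                values = rr$values)
    }
  }
  r
}

#' Normalized current blockade A/I0
#'
#' The fractional current amplitude of a capture event relative to the
#' open-substate current: `(i0 - i_off) / i0`. Values are dimensionless and
#' scale-invariant. A negative value (enhanced-current event, `i_off > i0`)
#' is returned with a warning.
#'
#' @param i0 open-substate current, pA (> 0).
#' @param i_off mean current of the captured event, pA.
#' @return numeric blockade fraction(s).
#' @examples
#' normalized_blockade(32.1, 2.9)   # deep hSUMO1-type blockade, ~0.91
#' normalized_blockade(18.2, 6.4)   # shallow EGFR mode-1 blockade, ~0.65
#' @export
normalized_blockade <- function(i0, i_off) {
  if (any(i0 <= 0)) stop("i0 must be positive", call. = FALSE)
  out <- (i0 - i_off) / i0
  if (any(out < 0)) {
    warning("enhanced-current event: i_off exceeds i0")
  }
  out
}

#' Fit a Gaussian mixture to blockade amplitudes
#'
#' Maximum-likelihood Gaussian mixture over the blockade fractions of
#' captured events, as used to resolve the two-peak amplitude distribution of
#' bimodal analyte recognition. Components are sorted ascending by mean, so
#' mode 1 is the shallow (low-amplitude) family.
#'
#' @param events an `event_table` (or data frame with `class` and
#'   `blockade_fraction` columns).
#' @param k number of mixture components.
#' @return Object of class `amplitude_mixture`: `peaks` tibble (`mean`, `sd`,
#'   `weight`), `logL`, `N`, `k`.
#' @export
fit_amplitude_mixture <- function(events, k = 2) {
  a <- amplitude_vector(events)
  if (length(a) < 10 * k) {
    stop("need at least 10 * k captured events (got ", length(a), ")",
         call. = FALSE)
  }
  fit <- mclust::Mclust(a, G = k, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) {
    fit <- mclust::Mclust(a, G = k, modelNames = "E", verbose = FALSE)
  }
  if (is.null(fit)) stop("amplitude mixture fit failed to converge", call. = FALSE)
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(rep_len(as.numeric(fit$parameters$variance$sigmasq), k))
  w <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  structure(list(
    peaks = tibble::tibble(mean = mu[ord], sd = sig[ord], weight = w[ord]),
    logL = fit$loglik, N = length(a), k = k
  ), class = "amplitude_mixture")
}

amplitude_vector <- function(events) {
  stopifnot(is.data.frame(events))
  a <- events$blockade_fraction[events$class == "captured"]
  a[is.finite(a)]
}

#' @export
print.amplitude_mixture <- function(x, ...) {
  cat(sprintf("<amplitude_mixture> k = %d, N = %d, logL = %.2f\n",
              x$k, x$N, x$logL))
  print(as.data.frame(x$peaks), row.names = FALSE)
  invisible(x)
}

#' Assign amplitude modes to events
#'
#' Labels each captured event with the maximum-posterior mixture component
#' (mode 1 = shallow/short-lived family). Ties go to the lower-index mode.
#' Released events inherit the mode of the following capture, so that
#' per-mode interevent (released) durations can be accounted.
#'
#' @param events an `event_table`.
#' @param mixture an `amplitude_mixture` with >= 2 peaks.
#' @return the event table with the `mode` column filled in.
#' @export
assign_modes <- function(events, mixture) {
  stopifnot(inherits(mixture, "amplitude_mixture"))
  if (nrow(mixture$peaks) < 2) {
    stop("mixture must have at least 2 peaks", call. = FALSE)
  }
  cap <- which(events$class == "captured")
  a <- events$blockade_fraction[cap]
  post <- vapply(seq_len(nrow(mixture$peaks)), function(i) {
    with(mixture$peaks[i, ], weight * stats::dnorm(a, mean, sd))
  }, numeric(length(a)))
  post <- matrix(post, nrow = length(a))
  mode_lab <- apply(post, 1, which.max)  # which.max: first (lower) index on ties
  events$mode[cap] <- as.integer(mode_lab)
  # released events take the mode of the following capture
  rel <- which(events$class == "released")
  nxt <- findInterval(rel, cap) + 1L
  events$mode[rel] <- ifelse(nxt <= length(cap),
                             events$mode[cap[nxt]], 0L)
  events
}
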