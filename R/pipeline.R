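#' Experiment configuration for the end-to-end pipeline
#'
#' Bundles a kinetic-scheme preset, the concentration series to simulate (or
#' analyze), trace acquisition parameters, detection and fitting settings
#' into one validated object consumed by [run_pipeline()].
#'
#' @param preset scheme preset (`"bimolecular"`, `"two_mode"`,
#'   `"interconversion"`).
#' @param rates named rate constants for the preset (see [kinetic_scheme()]).
#' @param levels optional per-state current levels (pA).
#' @param concentrations analyte concentrations, mol/L (may be empty: the
#'   pipeline then only simulates at concentration 0 and skips kinetics).
#' @param duration_s trace duration per concentration, s; alternatively give
#'   `target_events` to size each trace for an expected event count.
#' @param target_events expected number of capture events per concentration
#'   (overrides `duration_s` when given).
#' @param trace trace-rendering settings, a [trace_config()] (its duration
#'   and concentration fields are overridden per run).
#' @param threshold_fraction,spike_cutoff detection settings, see
#'   [detect_events()].
#' @param deadtime detection deadtime, s (NULL = filter rise time).
#' @param k_max,confidence dwell model-selection settings, see
#'   [llr_select()].
#' @param n_modes number of amplitude modes fitted (1 = unimodal analyte).
#' @param fit_topology optional rate-matrix topology also fitted and
#'   LLR-compared against its nested alternative (`"interconversion"`).
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @return a validated list of class `experiment_config`.
#' @export
experiment_config <- function(preset = "bimolecular",
                              rates = c(k_on = 1.12e8, k_off = 74.5),
                              levels = NULL,
                              concentrations = c(65e-9, 130e-9, 260e-9),
                              duration_s = NULL, target_events = 300,
                              trace = trace_config(),
                              threshold_fraction = 0.5, spike_cutoff = 0,
                              deadtime = NULL, k_max = 3, confidence = 0.95,
                              n_modes = 1, fit_topology = NULL, seed = 1L) {
  if (is.list(rates)) rates <- unlist(rates)
  if (is.list(levels)) levels <- unlist(levels)
  # YAML scalars like "1.12e8" (no sign on the exponent) arrive as strings
  if (is.character(rates)) {
    rates <- stats::setNames(as.numeric(rates), names(rates))
  }
  if (!is.null(levels) && is.character(levels)) {
    levels <- stats::setNames(as.numeric(levels), names(levels))
  }
  if (is.character(concentrations)) concentrations <- as.numeric(concentrations)
  if (is.list(trace) && !inherits(trace, "trace_config")) {
    trace <- do.call(trace_config, trace)
  }
  scheme <- kinetic_scheme(preset, rates = rates, levels = levels)  # validates
  stopifnot(all(concentrations >= 0), k_max >= 1,
            confidence > 0, confidence < 1, n_modes >= 1)
  structure(list(preset = preset, rates = rates, levels = levels,
                 scheme = scheme,
                 concentrations = as.numeric(concentrations),
                 duration_s = duration_s, target_events = target_events,
                 trace = trace, threshold_fraction = threshold_fraction,
                 spike_cutoff = spike_cutoff, deadtime = deadtime,
                 k_max = k_max, confidence = confidence,
                 n_modes = n_modes, fit_topology = fit_topology,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the simulate-detect-fit-summarize pipeline
#'
#' Executes the full closed-loop workflow for each configured concentration:
#' Gillespie simulation of the gating path, rendering to a noisy filtered
#' trace, baseline estimation, event idealization, (for multimodal analytes)
#' amplitude-mixture fitting and mode assignment, dwell-time model selection,
#' and finally concentration-series estimation of k_on, k_off and K_D.
#' Deterministic under a fixed seed; per-stage seeds are derived from the
#' master seed.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, traces (CSV), event tables
#'   (TSV) and the report (JSON) are written there.
#' @param psd logical; also compute a Welch PSD and noise classification on
#'   the first trace.
#' @return a list of class `run_report`: `config` echo, `per_concentration`
#'   tibble (tau_on, tau_off, chosen k, event counts), `series`, `kinetics`
#'   (k_on/k_off/K_D summary or NULL when < 1 concentration), `modes`,
#'   `noise`, `events` (list of event tables).
#' @export
run_pipeline <- function(config, out_dir = NULL, psd = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  scheme <- config$scheme
  concs <- config$concentrations
  concs <- concs[concs > 0]
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  if (length(concs) == 0) {
    # simulation-only run at zero concentration
    dur <- config$duration_s %||% config$trace$duration
    path <- simulate_dwells(scheme, 0, dur, seed = config$seed)
    tr <- render_trace(path, scheme, config$trace)
    message("no positive concentrations configured: kinetics skipped")
    return(structure(list(config = config, per_concentration = NULL,
                          series = NULL, kinetics = NULL, modes = NULL,
                          noise = NULL, events = NULL,
                          trace = tr), class = "run_report"))
  }

  rows <- list(); events_list <- list(); modes_tbl <- NULL; noise <- NULL
  mode_rows <- list()
  for (i in seq_along(concs)) {
    conc <- concs[i]
    seed_i <- config$seed + 1000L * i
    dur <- config$duration_s %||% expected_duration(scheme, conc,
                                                    config$target_events)
    path <- simulate_dwells(scheme, conc, dur, seed = seed_i)
    tc <- config$trace
    tc$duration <- dur; tc$concentration <- conc; tc$seed <- seed_i + 1L
    tr <- render_trace(path, scheme, tc)
    bl <- estimate_baseline(tr)
    ev <- detect_events(tr, bl,
                        threshold_fraction = config$threshold_fraction,
                        deadtime = config$deadtime,
                        deepest_level = min(scheme$states$level_pA),
                        spike_cutoff = config$spike_cutoff)
    if (config$n_modes > 1) {
      mix <- fit_amplitude_mixture(ev, k = config$n_modes)
      ev <- assign_modes(ev, mix)
      mt <- mode_interevent_tau(ev)
      mt$concentration_M <- conc
      mode_rows[[i]] <- mt
    }
    dw_on <- dwell_sample(ev, "released")
    dw_off <- dwell_sample(ev, "captured")
    sel_off <- llr_select(dw_off, k_max = config$k_max,
                          confidence = config$confidence, seed = seed_i)
    fit_on <- fit_exp_mixture(dw_on, k = 1)
    rows[[i]] <- tibble::tibble(
      concentration_M = conc, duration_s = dur,
      i0_pA = bl$i0, n_events = sum(ev$class == "captured" & !ev$censored),
      tau_on_s = fit_on$components$tau_s[1],
      tau_on_se_s = fit_on$components$se_tau_s[1],
      tau_off_s = mean(dw_off$durations) - dw_off$deadtime,
      tau_off_se_s = stats::sd(dw_off$durations) /
        sqrt(length(dw_off$durations)),
      k_off_components = sel_off$chosen_k
    )
    events_list[[i]] <- ev
    if (psd && i == 1) {
      noise <- fit_noise_model(welch_psd(tr))
    }
    if (!is.null(out_dir)) {
      tag <- sprintf("conc_%03.0fnM", conc * 1e9)
      write_trace(tr, file.path(out_dir, paste0("trace_", tag, ".csv")))
      write_events(ev, file.path(out_dir, paste0("events_", tag, ".tsv")))
    }
  }
  per_conc <- dplyr::bind_rows(rows)
  series <- concentration_series(per_conc$concentration_M,
                                 tau_on_s = per_conc$tau_on_s,
                                 tau_off_s = per_conc$tau_off_s,
                                 tau_on_se_s = per_conc$tau_on_se_s,
                                 tau_off_se_s = per_conc$tau_off_se_s,
                                 n_events = per_conc$n_events)
  kin <- if (nrow(series) >= 1) kinetics_summary(series) else NULL
  if (length(mode_rows) > 0) modes_tbl <- dplyr::bind_rows(mode_rows)

  interconv <- NULL
  if (!is.null(config$fit_topology) &&
      config$fit_topology == "interconversion") {
    ev1 <- events_list[[length(events_list)]]
    m_ind <- fit_scheme(ev1, "two_mode", concs[length(concs)],
                        seed = config$seed)
    m_ic <- fit_scheme(ev1, "interconversion", concs[length(concs)],
                       seed = config$seed)
    interconv <- compare_schemes(m_ind, m_ic, config$confidence)
  }

  report <- structure(list(config = config, per_concentration = per_conc,
                           series = series, kinetics = kin,
                           modes = modes_tbl, noise = noise,
                           interconversion = interconv,
                           events = events_list),
                      class = "run_report")
  if (!is.null(out_dir)) {
    write_report(report_summary(report), file.path(out_dir, "report.json"))
  }
  report
}

# trace duration expected to yield ~n capture events
expected_duration <- function(scheme, concentration, n_events) {
  q <- generator_matrix(scheme, concentration)
  rel <- scheme_class_index(scheme, "released")[1]
  rate_on <- -q[rel, rel]
  if (rate_on <= 0) return(10)
  # mean cycle = released dwell + mean captured dwell
  cap_idx <- scheme_class_index(scheme, "captured")
  koff <- -diag(q)[cap_idx]
  cycle <- 1 / rate_on + mean(1 / koff)
  1.15 * n_events * cycle
}

# JSON-friendly digest of a run report
report_summary <- function(report) {
  list(
    preset = report$config$preset,
    rates = as.list(report$config$rates),
    seed = report$config$seed,
    per_concentration = report$per_concentration,
    kinetics = report$kinetics,
    modes = report$modes,
    noise = if (!is.null(report$noise)) {
      list(classification = report$noise$classification,
           s_white = report$noise$s_white,
           a_flicker = report$noise$a_flicker,
           alpha = report$noise$alpha)
    },
    interconversion = if (!is.null(report$interconversion)) {
      list(llr = report$interconversion$llr,
           critical = report$interconversion$critical,
           superior = report$interconversion$superior)
    },
    version = as.character(utils::packageVersion("porekin"))
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$config$preset, "preset\n")
  if (!is.null(x$per_concentration)) {
    print(as.data.frame(x$per_concentration), row.names = FALSE)
  }
  if (!is.null(x$kinetics)) {
    cat(sprintf("k_on = %.3g M^-1 s^-1, k_off = %.3g s^-1, K_D = %.3g nM\n",
                x$kinetics$k_on_M1s1, x$kinetics$k_off_s1, x$kinetics$kd_nM))
  }
  invisible(x)
}
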