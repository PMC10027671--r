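# porekin

Single-molecule kinetic analysis for nanopore protein sensors.

Protein nanopore sensors with an external antibody-mimetic binder (e.g. a
monobody fused to a monomeric β-barrel pore) report individual
capture/release events of a protein analyte as resistive pulses: the open
pore conducts at a current *I*₀, an analyte bound at the binder reduces the
current to a blocked substate, and release restores *I*₀. The record of
alternating released durations τ_on and captured durations τ_off encodes
the binding kinetics of a *single* sensor molecule. `porekin` is an R
package for everyone working with such recordings (or designing such
sensors): it simulates realistic single-channel traces from kinetic
schemes, idealizes traces into event tables, and turns dwell statistics
into rate constants, affinities, mode probabilities, analyte
concentrations, and noise classifications.

## The model at the core

Gating is a continuous-time Markov chain over one released state `O_on` and
one or two captured substates `O_off(,i)`:

- released dwells are exponential with rate *k*_on·*C* (bimolecular
  association; *C* = analyte concentration), so the event frequency
  *f* = 1/τ_on = *k*_on·*C*;
- captured dwells have rate *k*_off (unimolecular dissociation), giving the
  equilibrium dissociation constant *K*_D = *k*_off/*k*_on;
- with two captured substates (bimodal recognition), dwell densities take
  the aggregated-Markov (phase-type) form
  *f*(t) = φ′ exp(*Q*_AA·t)(−*Q*_AA)**1**, and an optional interconversion
  extension adds direct exchange rates *k*₁₂, *k*₂₁ between the captured
  substates, tested against the independent-substate scheme by a
  log-likelihood-ratio (LLR) decision at confidence C = 0.95.

Dwell-time fits maximize a deadtime-truncated exponential-mixture
likelihood; the number of components is chosen by LLR with χ²(2) per added
component. Noise spectra are Welch periodograms classified as white vs 1/f
flicker by fitting S(f) = S_w + A_f/f^α.

## Worked example

Kinetic constants straight from dwell summaries — three concentrations,
their mean interevent and capture durations, and the resulting rate
constants and affinity:

```r
library(porekin)

ser <- concentration_series(
  c(65e-9, 130e-9, 260e-9),
  tau_on_s  = c(0.125, 0.069, 0.035),
  tau_off_s = c(0.015, 0.016, 0.014))

fit_kon(ser)$k_on_M1s1      # 110821642 -- slope of 1/tau_on vs C, ~1.11e8 M^-1 s^-1
fit_koff(ser)$k_off_s1      # 66.86508  -- mean of 1/tau_off, s^-1
compute_kd(1.12e8, 74.5)    # K_D = 6.65e-7 M = 665 nM
```

A fully closed loop — simulate a bimolecular sensor at three
concentrations, render noisy filtered traces, idealize, and re-estimate the
kinetics:

```r
cfg <- experiment_config(
  preset = "bimolecular",
  rates = c(k_on = 1.12e8, k_off = 74.5),   # generator truth
  levels = c(O_on = 32.1, O_off = 2.9),     # pA at +40 mV
  concentrations = c(65e-9, 130e-9, 260e-9),
  target_events = 350, seed = 1)
rep <- run_pipeline(cfg)
rep
#> <run_report> bimolecular preset
#>  concentration_M duration_s    i0_pA n_events   tau_on_s ... k_off_components
#>          6.5e-08   60.69115 32.12335      388 0.14114449 ...                1
#>          1.3e-07   33.04692 32.12067      365 0.07724133 ...                1
#>          2.6e-07   19.22480 32.09988      381 0.03689567 ...                1
#> k_on = 1.04e+08 M^-1 s^-1, k_off = 73.2 s^-1, K_D = 706 nM
```

The recovered *k*_on, *k*_off and *K*_D sit within sampling error (a few
percent at ~380 events per concentration) of the configured truth, and the
LLR selection reports single-exponential capture durations
(`k_off_components == 1`) at every concentration, as it should for a
two-state scheme.

Quantifying an analyte in a noisy background from its long-lived specific
mode, given a calibrated mode-2 association constant:

```r
estimate_concentration(tau_on = 1.7, k_on = 2.9e7,
                       se_tau_on = 0.5, se_k_on = 0.2e7)
#> concentration_nM = 20.3, se_nM = 6.13
```

Each fitted object has broom-style `tidy()`/`glance()` methods and a
ggplot2 `autoplot()` (traces, dwell histograms with fit overlays, amplitude
mixtures, spectra, concentration series).

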