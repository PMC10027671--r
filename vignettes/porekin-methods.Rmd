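---
title: "Single-molecule kinetics of nanopore protein sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule kinetics of nanopore protein sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

porekin analyzes single-channel current recordings from protein nanopore
sensors that carry an external binder (an antibody-mimetic monobody fused to
a monomeric β-barrel pore). A free sensor conducts at an open-substate
current $I_0$; capture of a single analyte molecule at the binder switches
the pore to a lower conducting substate, and release restores $I_0$. The
alternating record of released (interevent) durations $\tau_{on}$ and
captured durations $\tau_{off}$ is a direct readout of binding kinetics at
single-molecule resolution. This vignette documents the models the package
implements, the defaults it chooses where the underlying physics does not
dictate one, and what the synthetic-data tests do and do not demonstrate.

## The kinetic model

Gating is modelled as a continuous-time Markov chain over one released state
and one or two captured substates:

* **bimolecular** — `O_on <-> O_off` with association rate $k_{on} C$
  (units: $k_{on}$ in M$^{-1}$s$^{-1}$, analyte concentration $C$ in mol/L)
  and dissociation rate $k_{off}$ (s$^{-1}$). Released dwells are
  exponential with mean $\tau_{on} = 1/(k_{on} C)$, captured dwells with
  mean $\tau_{off} = 1/k_{off}$, and $K_D = k_{off}/k_{on}$.
* **two_mode** — two independent captured substates `O_off1`, `O_off2`
  (distinct blockade depths and lifetimes), entered from `O_on` with rates
  $k_{on,1} C$ and $k_{on,2} C$. This describes bimodal recognition: a
  shallow/short-lived mode 1 and a deep/long-lived mode 2.
* **interconversion** — two_mode plus direct exchange between the captured
  substates at rates $k_{12}$, $k_{21}$ (s$^{-1}$, concentration
  independent).

`simulate_dwells()` realizes the chain by the Gillespie algorithm, starting
in the released state (the physically sensible initial condition after
reconstitution, and the one that makes the first dwell analyzable). The
final dwell is right-censored and excluded from dwell statistics, the
standard convention in single-channel analysis.

## The trace forward model

`render_trace()` converts a state path into a realistic recording:
piecewise-constant current at per-state levels (pA, positive-current
convention with blockades deflecting toward zero), plus white Gaussian
instrument noise, plus optional $1/f^\alpha$ flicker noise, low-pass
filtered with a digital 8-pole Bessel filter and sampled at `sampling_rate`
(default 50 kHz, filter cutoff 3 kHz — typical patch-clamp acquisition
settings for this kind of sensor).

Two components are implemented in the package because no installed library
provides them:

* **Bessel filter.** The analog prototype is derived from the reverse
  Bessel polynomial (poles via `polyroot`), normalized numerically to a
  −3 dB cutoff, pre-warped, and discretized by the bilinear transform;
  `signal::filter` applies the recursion. The implementation is validated
  against the patch-clamp rule of thumb for the 10–90% step rise time,
  $T_r \approx 0.3321/f_c$ (≈111 µs at 3 kHz).
* **Flicker noise.** Synthesized by inverse-FFT spectral shaping with
  independent random phases so that the one-sided PSD is
  $A_f/f^\alpha$ (default $\alpha = 1$), with `flicker_amplitude` $A_f$ in
  pA²·Hz$^{\alpha-1}$ at 1 Hz. The default biofluid-like setting
  $A_f = 0.1$ places the 10 Hz flicker level two orders of magnitude above
  the white floor of a 1 pA instrument noise at 50 kHz, which reproduces the
  qualitative white-to-flicker transition seen when serum is added while
  keeping total added variance near 1 pA².

## Event idealization

`detect_events()` uses half-amplitude threshold idealization: a capture
opens when the current falls below
$I_0 - \theta\,(I_0 - I_{deepest})$ (default $\theta = 0.5$, deepest level
0, i.e. $I_0/2$) and closes on re-crossing. The vendor "single-channel event
search" used for the original recordings is not specified further;
half-amplitude crossing is the standard, well-characterized choice.

Events shorter than the deadtime are discarded and their samples merged into
the flanking events of the other class — in both directions, so brief noise
re-openings inside a long blockade do not split it. The default deadtime is
the filter rise time $T_r = 0.3321/f_c$: shorter events are
amplitude-attenuated below threshold and cannot be detected reliably. Event
mean currents exclude the first $T_r$ worth of samples (filter rise), and
blockade fractions are $A/I_0 = (I_0 - \bar I_{event})/I_0$.

The baseline $I_0$ is the mean of the highest-mean component of a Gaussian
mixture fitted to the all-points histogram (`mclust`); this is robust to
tens of percent of captured-time occupancy. For biofluid-type records,
`spike_cutoff` optionally removes captured events shorter than a
user-chosen duration (off by default; ~5 ms is a sensible setting when
nonspecific serum spikes in the low-millisecond range must be separated from
~1 s specific captures).

Amplitude modes are resolved by a Gaussian mixture over blockade fractions
(`fit_amplitude_mixture`, delegated to `mclust` with unequal variances) and
assigned by maximum posterior with ties to the lower-index mode
(`assign_modes`). Assignment is hard rather than probabilistic: the
downstream per-mode dwell accounting needs an unambiguous pairing of
amplitude families with duration families.

## Dwell-time inference

`fit_exp_mixture()` maximizes the deadtime-truncated mixture likelihood

$$ f(t) = \frac{\sum_i (p_i/\tau_i)\, e^{-t/\tau_i}}
               {\sum_i p_i\, e^{-d/\tau_i}}, \qquad t \ge d, $$

with the closed form $\hat\tau = \bar t - d$ at $k = 1$ and BFGS on a
softmax/log parametrization otherwise, from a log-duration quantile split
plus ten seeded random restarts. Standard errors come from the observed
Fisher information (numerical Hessian in the natural parametrization).
Left truncation is the only deadtime correction applied: at the rate
magnitudes this package targets ($k_{off} \lesssim 75$ s$^{-1}$,
deadtime ~0.1 ms) the missed-event bias is below 1%, so a full missed-event
(exact retrigger) correction is out of scope and documented as a
limitation.

`llr_select()` compares $k$ against $k+1$ components and accepts the richer
model only when $2\Delta\log L$ strictly exceeds the $\chi^2$ quantile at
confidence $C$ (default 0.95) with 2 degrees of freedom per added component
(one time constant, one weight). The $\chi^2$ reference is the conventional
choice despite the boundary non-regularity of mixture testing; simulation
shows it is conservative here (false acceptance of a second component well
under the nominal 5% at $n = 1000$), which is the safe direction for
reporting the number of binding modes.

## Rate-matrix (aggregated Markov) dwell densities

For multi-substate schemes the captured-class dwell density is the
phase-type form

$$ f(t) = \varphi^\top e^{Q_{AA} t} (-Q_{AA}) \mathbf{1}, $$

with $Q_{AA}$ the within-class generator block and $\varphi$ the entry
distribution given by the stationary flux into the class (`dwell_pdf`,
`dwell_cdf`; spectral decomposition of $Q_{AA}$, which is 2×2 with real
eigenvalues for all admissible rates). With $k_{12} = k_{21} = 0$ this
reduces exactly to the entry-flux-weighted exponential mixture.

**Why the interconversion likelihood uses capture-substate labels.** The
marginal captured-dwell density of any two-substate interconverting scheme
is an order-2 phase-type density; over the parameter range of interest the
independent-substate model — whose entry weights and exit rates are free —
spans the same two-exponential family. Fitting both topologies to unlabeled
dwell durations therefore yields $2\Delta\log L \approx 0$ regardless of
the true $k_{12}, k_{21}$: the comparison has no power. The information
that distinguishes the topologies is which substate a capture *enters*
(observable through the blockade amplitude at the start of the event, and
known exactly for simulated paths). `fit_scheme()` therefore uses, when
mode labels are available, the joint likelihood of (entry label, duration):
under two_mode this factorizes into a multinomial entry times per-mode
truncated exponentials (closed-form MLE); under interconversion the
duration term is the entry-conditional phase-type density
$[e^{Q_{AA}t}(-Q_{AA})\mathbf 1]_m$. The two likelihoods are nested over
the same data, so `compare_schemes()` applies a regular LLR decision with
df = 2. On unlabeled dwell records `fit_scheme()` falls back to the
marginal density and model comparison is (correctly) uninformative. The
boundary at $k_{12} = k_{21} = 0$ again makes the $\chi^2(2)$ reference
conservative, which matches the use of the test as a guard against
over-claiming interconversion.

Amplitude *sequences within* a capture (an interconverting event changes
depth mid-blockade) are not modelled; entry labels are the minimal
observable that restores identifiability, and mid-event level tracking is
left out of scope.

## Concentration-series kinetics and quantification

`fit_kon()` estimates $k_{on}$ as the least-squares slope of $1/\tau_{on}$
versus $C$ constrained through the origin — the estimator implied by strict
1:1 proportionality of capture frequency to concentration in a bimolecular
association — and reports a free-intercept fit as a lack-of-fit diagnostic
(on simulated data the intercept is statistically zero). Fits are
unweighted by default. `fit_koff()` averages $1/\tau_{off}$ across
concentrations (dissociation is unimolecular, hence concentration
independent; a slope diagnostic tests this). `compute_kd()` forms
$K_D = k_{off}/k_{on}$ with first-order error propagation, treating an
unsupplied standard error as zero rather than poisoning the propagation.

**Per-mode interevent durations.** For bimodal data, $\tau_{on,i}$ is
defined as the released time between consecutive mode-$i$ captures
(equivalently, total non-censored released time divided by the number of
mode-$i$ events; `mode_interevent_tau`). Under the Markov model this equals
$1/(k_{on,i} C)$, which is what makes the per-mode association constants
$k_{on,i} = 1/(\tau_{on,i} C)$ well defined and sum-consistent with the
total capture rate. The superficially similar definition "duration of the
released event immediately preceding a mode-$i$ capture" would, by
memorylessness, give identical means for both modes and cannot yield
distinct $k_{on,i}$; it was therefore rejected.

`estimate_concentration()` inverts the calibrated frequency relation
$C = 1/(\tau_{on} k_{on})$; in a noisy background the long-lived specific
mode's $\tau_{on,2}$ and its serum-free calibration $k_{on,2}$ quantify the
analyte while ignoring nonspecific spikes. `conductance()` is the trivial
$G = I/\Delta\psi$ reporting helper (pA/mV = nS).

## Noise spectra

`welch_psd()` is a standard Welch estimator — Hann window, 50% segment
overlap, one-sided density normalized so $\int S\,df$ equals the signal
variance; these conventions are fixed so regression tests are meaningful.
`fit_noise_model()` fits $S(f) = S_w + A_f/f^\alpha$ on log-spaced bins in
log-space over 2–1000 Hz by default (below the anti-aliasing corner). A
spectrum is classified `"flicker"` only if the fitted flicker term carries
more than half the power at 10 Hz *and* the model-free low-frequency excess
over the plateau exceeds threefold; the second condition removes a genuine
degeneracy ($\alpha \to 0$ mimics a white floor), and $\alpha$ is bounded
below at 0.3 for the same reason. The frequency band for judging the
transition is a package choice; the classification is insensitive to it
within 2–1000 Hz for the default generator settings. Note that gating
itself contributes low-frequency (Lorentzian) power, so the white/flicker
classification is most meaningful on event-free baseline stretches or as a
comparison between matched recordings with and without the biofluid
background.

## Orchestration, formats, problem sizes

`run_pipeline()` chains simulate → render → detect → (amplitude modes) →
dwell selection → concentration-series kinetics, deterministic under a
master seed with per-stage derived seeds, and writes traces (CSV
`time_s,current_pA`), event tables (TSV), and a JSON report. Configurations
are YAML (`read_config`). A thin command-line wrapper with subcommands
(`simulate`, `detect`, `fitdwell`, `kinetics`, `psd`, `quantify`,
`reproduce-paper`) ships in `inst/cli/porekin.R`; the R functions are the
primary interface. Trace I/O is CSV-only: no HDF5 bindings are declared, and
a 60 s, 50 kHz trace round-trips in seconds.

Test and reproduction problem sizes are chosen to give comfortable
statistical margins at interactive runtimes: ~500 events per concentration
for closed-loop rate recovery (sampling s.e. ≈ 4%, checked at 10%), 200
replicates of $n=1000$ for LLR calibration, 100 replicates of ~1400-event
records for the interconversion power/null properties, $10^5$ Gillespie
dwells for the phase-type density cross-check, and 100 + 100 rendered
2.7 s traces for noise classification.

## What the synthetic tests do and do not show

The generator emulates: exponential gating at published rate magnitudes
($k_{on}$ ~ $10^7$–$10^8$ M$^{-1}$s$^{-1}$, $k_{off}$ ~ 1–75 s$^{-1}$),
realistic open currents (18–40 pA at +20/+40 mV), Gaussian instrument
noise, Bessel filtering, and serum-like flicker noise. It does not emulate:
baseline drift and 50/60 Hz pickup, gating artifacts of the pore itself,
mid-event amplitude substructure, slow sensor inactivation, or correlated
(non-renewal) gating beyond the Markov schemes. Passing closed-loop tests
therefore demonstrates the estimators' correctness and calibration under
the stated model, not robustness to every pathology of real recordings;
the deadtime, spike-cutoff and diagnostic-intercept machinery are the
intended handles for such data.

Known limitations: no exact missed-event correction; hard (not
probabilistic) mode assignment; interconversion inference requires entry
labels (see above); CSV-only trace I/O; standard errors are asymptotic
(observed information), which can be optimistic for small event counts or
nearly collapsed mixture components (the fit warns when component time
constants are within a factor of 1.5).
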