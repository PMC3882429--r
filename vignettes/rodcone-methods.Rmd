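---
title: "Models and methods behind rodcone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rodcone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodcone)
```

`rodcone` simulates and analyses photovoltage recordings from mouse rods
and cones coupled through Cx36 gap junctions. This vignette documents
the models, their assumptions, the tunable parameters with their
defaults and units, and the numerical choices — in particular, which
values are anchored to published measurements and which are calibration
choices of this package.

## The cone spectral model

Most mouse cones co-express M-opsin (peak 508 nm) and S-opsin (peak
359 nm) in a dorsoventral gradient. The package predicts a cone's
flash-response profile from a single hyperbolic saturation function

$$R(I) = R_\max \frac{I}{I + I_{1/2}},$$

whose half-saturating strength is set by the cone's relative absorbance
at the stimulus wavelength. The reference normalized flash sensitivity
of a cone probed at its preferred wavelength is
$S_n = 0.00042\ \mathrm{photons^{-1}\,\mu m^2}$; because the small-signal
slope of the normalized hyperbola is $1/I_{1/2}$, this is equivalent to
$I_{1/2} = 1/S_n \approx 2381\ \mathrm{photons\,\mu m^{-2}}$.

The absorbance weight table is fixed by four anchors: each pigment
carries weight 1 at its own test wavelength (M at 520 nm, S at 365 nm);
M-opsin at 365 nm (the β-band) is 0.2 of maximum; S-opsin at 520 nm is
$10^{-4}$ (4 log-units down); rhodopsin is $1/2.2$ as sensitive at
365 nm as at 520 nm. A mixed cone with M-fraction $f_M$ has relative
sensitivity $f_M w_M(\lambda) + (1 - f_M) w_S(\lambda)$ under the
assumption that all cones express the same total opsin, and its
effective half-saturation is the reference $1/S_n$ divided by that
weight. Two consequences the tests exercise: the product of effective
half-saturation and relative sensitivity is invariant across mixes, and
the intrinsic green/UV preference crosses unity at
$f_M = 0.9999/1.7999 \approx 0.556$.

Two deliberate simplifications. First, M at 520 nm is taken as exactly
1 although the M peak sits at 508 nm; a template correction (≲3%)
would require an absorbance template the model does not carry. Second,
the two published opsin-gradient models are not re-implemented; only
their averaged outputs are tabulated (`m_fraction_for_latitude()`:
64%, 24%, 4.7%, 1.2% and 0% M-opsin for the dorsalmost to ventralmost
latitudes and pure-S cones). User-supplied fractions enter through
`opsin_mix()`.

## The coupled-photoreceptor equivalent circuit

`solve_steady_state()` solves a two-node resistive network: a cone node
and a lumped rod-pool node (per-rod conductances times the convergence
`N_rods`, default 32), each carrying a light-sensitive conductance
reversing at `E_OS` (default 0 mV) and a leak reversing at `E_leak`,
joined by the summed junctional conductance
$g_{GJ} = g_{pair} N_{rods}$ (default $121 \times 32 = 3872$ pS,
presented as 3900 pS at two significant figures). Units are pS and mV
throughout, so branch currents are pS·mV = fA, reported in pA.

The network is solved quasi-statically — no membrane capacitance.
Response kinetics are carried entirely by the waveform templates of the
photoresponse module, so the circuit introduces no temporal distortion.
This is intentional: the circuit is used for steady-state attenuation
and polarity arguments, and the observed acceleration of rod signals
recorded in cones (time-to-peak 197 ms versus 258 ms in rods) is imposed
phenomenologically rather than explained mechanistically; an RC filter
would instead *slow* the coupled signal.

Leak and dark photoconductance magnitudes are not published; the
defaults are calibration choices pinned to two printed dark potentials.
With `E_leak = -65` mV, a cone with `g_photo = 420` pS and
`g_leak = 880` pS rests at exactly $-44$ mV, and a rod with 300/480 pS
rests at exactly $-40$ mV (880/1300 · 65 = 44 and 8/13 · 65 = 40; the
round conductances were chosen to make the dividers land exactly on the
printed potentials, with the cone's dark photocurrent
$420\ \mathrm{pS} \times 44\ \mathrm{mV} \approx 18$ pA in the
physiological range).

`classify_polarity()` encodes the polarity prediction for a cone held
depolarized beyond `E_OS`: the junctional current depolarizes its rods
beyond, at, or below `E_OS`, producing concordant depolarizing dim and
bright responses, absent dim responses with reversed bright responses,
or opposite polarities, respectively. The tolerance around `E_OS`
defaults to 0.5 mV, the scale of the filtered noise floor. Cx36
transjunctional gating is a disabled-by-default hook
(`gating_config()`): no quantitative gating curve is published, so when
enabled the package uses a symmetric sigmoid with a configurable
half-attenuation voltage and a conductance floor (0.5), evaluating to
the midpoint 0.75 at the half-attenuation voltage.

## Photoresponse templates

The waveform generators are phenomenological; no published functional
form exists for these photovoltages, so shapes are chosen to honour the
printed kinetics anchors.

- **Dim flash**: an alpha-like lobe $(t/T)^n e^{n(1-t/T)}$ peaking at
  exactly the time-to-peak $T$, with $n = 4$ (configurable) putting the
  width at half amplitude in the several-hundred-ms range. Rod default
  $T = 258$ ms (loose seal); the rod signal recorded in a cone uses the
  coupled default $T = 197$ ms; the intrinsic cone response uses 70 ms
  (figure-scale calibration).
- **Saturating flash**: a fast exponential trough (30 ms rise constant)
  to $-R_\max$, a plateau of duration
  $T_{sat}(I) = \tau_d \ln(I/I_{ref})$, then exponential recovery
  ($\tau_{rec} = 1$ s). $\tau_d = 0.5/\ln 2 \approx 0.72$ s and
  $I_{ref} \approx 298\ \mathrm{photons\,\mu m^{-2}}$ solve
  $T_{sat}(1570) = 1.2$ s and $T_{sat}(3140) = 1.7$ s, keeping both
  bright strengths inside the stated 1–2 s saturation window.
- **Intensity–response**: rod amplitudes follow the hyperbola with
  `i_half = 30` photons·µm⁻² and `r_max = 25` mV — neither is printed;
  they are calibrated so the 16.6 photons·µm⁻² dim flash gives a large
  sub-saturating response (>0.2 R_max) while 1570 saturates, and so that
  the same dim flash leaves a cone's intrinsic response below 1% of its
  R_max (12 mV default). Ultraviolet strengths are divided by the
  spectral shift factor 2.2 before entering the hyperbola.
- **Spectral amplitudes**: the measured dim G/UV amplitude ratio (2.7)
  exceeds the bound a pure 2.2 sensitivity shift can produce (the
  equal-strength amplitude ratio of a shifted hyperbola is at most the
  shift factor, approached only in the deep-linear limit). The two are
  therefore independent generator parameters: profile generation uses
  the 2.2 shift, while spectral-protocol dim UV responses are scaled by
  the configured amplitude ratio directly.
- **Backgrounds**: a background at or above
  6100 photons·µm⁻²·s⁻¹ (520 nm) zeroes rod-pathway responsiveness;
  after offset, responsiveness recovers as
  $1 - e^{-\Delta t/\tau_{bg}}$ with $\tau_{bg} = 50$ s, placing the
  90% point at $50 \ln 10 \approx 115$ s — the calibration target of
  "near control after ~2 min". Intrinsic cone responses are never
  scaled by this factor.

## Stimulus protocols

`build_kinetics_protocol()` delivers, per sweep, dim G (16.6), bright G
(1570) and dim G at 1, 2.5 or 4 s after the bright flash, all 520 nm.
`build_spectral_protocol()` delivers dim G/UV pairs (equal photon
strength), bright (3140) G/UV pairs, and pre-flashed bright tests where
a green rod-saturating pre-flash (default 1570, 0.5 s before the test —
inside the >1 s rod saturation window; neither value is printed)
unmasks the cone's intrinsic spectral preference.
`build_background_protocol()` wraps control deliveries, the 5-min
background (bright flashes only during the epoch — no dim flashes) and
post-offset dim deliveries every 30 s for recovery tracking.

Validation enforces the ≥12 s spacing between consecutive bright
flashes on the absolute timeline; a pre-flash/test pair is exempt, the
protocol explicitly prescribing its short gap. Flash durations are
bookkept in the 1–10 ms range (default 5 ms) but flashes are treated as
instantaneous for waveform timing. `photon_flux_from_power()` converts
measured power densities with $\Phi = P\lambda/(hc)$.

## The synthetic-recording generator

`generate_recording()` composes the pieces. Rod traces are the dark
potential plus flash templates, with each flash scaled by (i) the
background responsiveness factor and (ii) the fractional recovery since
the most recent saturating flash — so a dim flash delivered 1 s after a
1570 photons·µm⁻² flash produces no response (the rod is still inside
its 1.2 s saturation), and a bright test after a rod-saturating
pre-flash is silent. Cone traces add an intrinsic component (fast
kinetics, spectral-model amplitudes, unaffected by rod saturation or
backgrounds) to the rod-pool component attenuated through the
quasi-static divider at the instantaneous junctional conductance.

Coupling growth during a cone recording is a monotone logistic
trajectory from `g0 · g_max` toward `g_max` — the published time courses
are qualitative sigmoid-like fits with no stated functional form or
population distribution, so the trajectory family and the cohort
distributions (`g0 ~ U(0.1, 0.9)`, `g_max ~ U(2500, 3872)` pS,
rate `~ U(0.2, 1)` min⁻¹ at 24 °C) are configuration, not published
facts. Blocker superfusion multiplies the trajectory by
$e^{-\Delta t/\tau}$ with $\tau = 8$ min (minutes-scale
pharmacodynamics); rods are unaffected. Rundown modes: patched rods
drift their time-to-peak from the loose-seal value toward the
patched-rod mean (288 ms) over ~15 min; whole-cell cones lose intrinsic
amplitude with a 20-min constant; loose-seal recordings are identity.

Noise is additive white Gaussian at 1.5 mV raw SD, chosen so the 20-ms
box-car-filtered baseline has SD ≈ 0.15 mV — making a ~0.3 mV response
near-threshold at the 3σ detection criterion (0.45 mV). The sampling
rate defaults to 5 kHz (acquisition hardware rate unstated). All
randomness flows from one seed; generation saves and restores the
global RNG state, and cohorts derive per-cell seeds from the master
seed, so cohorts are pure functions of configuration and seed.

Population presets: loose-seal rod dim-flash TTP ~ Normal(258, 25) ms,
patched rods Normal(288, 51) ms, coupled-cone dim TTP
Normal(197, 35) ms, all truncated at zero; the rod dim G/UV ratio is
Normal(2.7, 0.57) — the between-cell SD recovered from the reported SEM
of 0.2 at n = 8. The 36 °C preset uses faster kinetics (rod TTP 140 ms,
recovery constant 0.5 s — calibration, not printed) and modest
junctional conductances U(60, 260) pS so noiseless coupled dim-flash
amplitudes fall within the 0.28–1.70 mV band observed near body
temperature.

What the generator does *not* emulate: photon shot noise, the
phototransduction cascade, cone–cone coupling, residual rod responses
after pre-flashes, per-rod network topology, capacitive transients, or
the mechanistic cause of the coupling increase. Passing tests therefore
show that the analysis pipeline recovers the parameters of *this*
statistical model of the data, not that it would be unbiased on every
feature of real recordings.

## The measurement pipeline

Traces are box-car filtered with a 20-ms running window (centred,
truncated at edges). For each flash, the baseline is the mean over a
200-ms pre-flash window. Responses that ride the recovery tail of a
preceding bright flash are handled by three drift-aware rules:

1. deflections are measured relative to the baseline's linear trend
   extrapolated through the search window, with the slope estimated on
   the *unfiltered* baseline (so its t-statistic is honest) and applied
   only when it is clearly non-zero (|t| ≥ 3) — a flat baseline is
   never tilted by a noise-fit slope;
2. dim-flash peaks must be interior local extrema that are also
   extremal at the filter-window scale; and
3. they must be transient — the deflection must fall back below half
   the candidate peak later in the window, which a monotone recovery
   drift never does.

A dim flash delivered while the cell is still saturated therefore
measures at the noise floor rather than reporting the drift itself.
Search windows default to 1 s (dim) and 400 ms (bright fast peak); the
plateau is the mean deflection 0.4–0.6 s post flash; ties in the peak
search resolve to the earliest sample. None of these window lengths is
published; all are configurable. With `refine_peak = TRUE` (used by the
cohort helpers), the dim-flash peak is refined by a least-squares
parabola over ±2 filter windows: the vertex position de-biases the
time-to-peak (the sample argmax drifts rightward on the flat top of a
noisy response) and the vertex value removes the upward amplitude bias
of extremum selection in noise — which would otherwise bias G/UV
amplitude ratios downward, since it inflates the smaller UV amplitude
by more in relative terms.

`fit_michaelis_menten()` is deterministic: a 0.02-decade log-grid
search over `i_half` with `r_max` solved analytically at each
candidate, then 1-D refinement (`stats::optimize`). `mann_whitney()`
enumerates all group assignments exactly (tie-aware) for combined
n ≤ 12 and otherwise uses the normal approximation with tie and
continuity corrections; `stats::wilcox.test` serves as an independent
cross-check in the tests, not as the implementation.
`extrapolate_initial_coupling()` fits an ordinary least-squares line to
the dim-flash amplitudes within the first 2 min of recording (the
early-window length is a documented choice), evaluates it at time zero,
floors at 0, and reports a confidence flag based on the slope standard
error. "Near control" recovery after a background is operationalized as
≥90% of the pre-background control amplitude. No multiple-testing
correction is applied anywhere: the analyses report single pairwise
comparisons.

## Problem sizes and reproducibility

The cohort analyses use the study-sized cohorts throughout: 24 coupled
cones and 23 loose-seal rods under the kinetics protocol, 8 rods under
the spectral protocol, and a single noise-free rod for the background
recovery, each recording 50–700 s at 5 kHz. `scripts/acceptance.R`
regenerates all of these from scratch from one seed.

## Known limitations

- The quasi-static circuit cannot reproduce capacitive filtering or the
  mechanism of the rod-to-cone kinetic speed-up; the speed-up is an
  imposed parameter.
- Superposition of flash templates is linear apart from the
  saturation/recovery scaling; very dense flash schedules could in
  principle exceed physiological bounds.
- The dim-flash measurement at the 1-s post-bright delay reads the
  noise floor by design; distinguishing a genuinely absent response
  from a sub-threshold one requires sweep averaging, as in practice.
- Michaelis–Menten fits assume homoscedastic errors; no weighting is
  applied.
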