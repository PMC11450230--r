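---
title: "A four-state kinetic model of high-affinity K+/H+ symport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A four-state kinetic model of high-affinity K+/H+ symport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hak5kin)
```

## The transport cycle

High-affinity potassium uptake in plant roots is carried by HAK/KUP/KT
transporters that couple one K+ to one H+ per cycle.  `hak5kin` models this
symport as a four-state cycle:

* **C1** — empty carrier, binding sites facing the bath;
* **C2** — external H+ bound (second-order rate `k12_0 * [H+]o`, reverse
  `k21`);
* **C3** — H+ and K+ bound (second-order `k23_0 * [K+]o`, reverse `k32`);
* **C4** — empty carrier facing the cytosol, reached by a
  voltage-independent conformational step `k34` that releases both ions
  inside; the reverse step is third order, `k43_0 * [H+]i * [K+]i`, lumping
  internal rebinding and return.

The loaded carrier (C3) is electroneutral; the empty carrier carries two
negative charges, so the C4 -> C1 return step moves charge.  It is treated
as passage over a single symmetric Eyring barrier:

$$k_{14} = k_{14}^0 e^{FV/RT}, \qquad k_{41} = k_{41}^0 e^{-FV/RT},$$

which makes `k14 * k41` voltage independent — a property the test suite
asserts.  Hyperpolarisation (more negative V) accelerates the return of the
empty inward-facing carrier to the bath-facing state and thereby pulls the
cycle in the uptake direction.

Microscopic reversibility ties the constants together,

$$k_{41}^0 k_{12}^0 k_{23}^0 k_{34} = k_{14}^0 k_{21} k_{32} k_{43}^0,$$

so only seven rates are free.  `kinetic_params()` always recomputes one
designated constant (by default `k43_0`, because it multiplies the tiny
internal product `[H+]i [K+]i` and therefore perturbs simulated curves
least) and refuses parameter sets that violate the identity.

## Steady state, current, and reversal

The stationary occupancies follow from the King–Altman procedure: each
state's occupancy is a sum of four directed spanning-tree rate products
divided by the sum of all sixteen (`king_altman_terms()`,
`king_altman_occupancies()`).  The transported current is

$$I = 2 e N (k_{14} C_1 - k_{41} C_4),$$

with `e` the elementary charge and `N` the transporter count; the factor 2
reflects the two charges of the empty carrier.  The same quantity has a
factored closed form whose numerator is proportional to
$[H^+]_i[K^+]_i e^{FV/RT} - [H^+]_o[K^+]_o e^{-FV/RT}$;
`steady_state_current()` evaluates both routes and returns the
inward/outward decomposition `I_minus`/`I_plus`.  Inward (uptake) current
is negative, matching TEVC sign conventions.  Setting the numerator to
zero gives the reversal potential

$$V_{rev} = \frac{RT}{2F}\ln\frac{[H^+]_o[K^+]_o}{[H^+]_i[K^+]_i},$$

independent of the rate constants.

Because closed-form King–Altman algebra is easy to mistranscribe, the
package carries an independent oracle, `numeric_occupancy_oracle()`, which
solves the master-equation null space directly; the suite requires
agreement to 1e-9 relative on randomized rate sets.  (One printed form of
the proton-affinity reduction contains a term `k41*k43` where the spanning
trees require `k14*k43`; the package uses the tree-consistent form, which
is also what the numeric oracle confirms.  With internal products zeroed
the two forms coincide.)

## Apparent Michaelis parameters

At fixed voltage and co-substrate the cycle's denominator is linear in the
varied external concentration, so the inward current is *exactly*
Michaelis–Menten in `[K+]o` (and in `[H+]o`).  `km_imax_potassium()` and
`km_proton()` evaluate the closed-form `K_K`, `K_H` and saturating
currents; `voltage_scan()` tabulates them over a voltage grid.  The tests
verify the reductions against half-saturations located by grid search and
bisection on the full current, with internal products zeroed — the pure
influx regime in which the reduction is derived.

Two qualitative signatures of the calibrated default set mirror the
recorded behaviour of the wild-type transporter: the apparent K+ affinity
is only weakly voltage dependent (the K+ site sits outside the membrane
field), while the apparent H+ affinity tightens steeply and monotonically
with hyperpolarisation, because the voltage-dependent return step competes
with proton debinding.

## Units and defaults

| Quantity | Interface unit | Default | Why |
|---|---|---|---|
| voltage | mV | -120 | standard holding potential in the assays |
| concentrations | mol/L | `[K+]o` 200 uM, pH_o 4.5 | typical test solution |
| internal | mol/L | `[K+]i` 100 mM, pH_i 7.1 | cytosolic values measured in oocytes |
| temperature | K | 298.15 | room-temperature electrophysiology; RT/F = 25.693 mV |
| current | A (nA in printouts) | — | TEVC scale |

The temperature of the original recordings is not stated anywhere in the
source material; 298.15 K is a documented, overridable convention.

## Calibration of the default rate constants

The numeric values of the original model's rate table are not available,
so the shipped defaults are **calibrated, not copied**.
`calibrate_default_params()` fixes a structural regime (the relative
magnitudes `k32/k34`, `k14_0/k41_0`, and the K+ binding scale) chosen so
the closed-form reductions reproduce the qualitative voltage and mutant
behaviour above, and then adjusts three log-scale knobs by
Levenberg–Marquardt against three printed wild-type observables:

* `K_K` = 23.56 uM at -120 mV, pH 4.5 (sets the H+ debinding rate `k21`);
* `K_H` = 4.81 uM at -120 mV, 200 uM K+ (sets the H+ binding constant
  `k12_0`);
* saturating current 417 nA at -140 mV (sets the transporter count `N`).

Three knobs against three targets makes the fit determined; the procedure
is deterministic (fixed start, no random restarts) and converges to
relative residuals below 1e-10.  `N` and the absolute rate magnitudes are
confounded in the current scale — only their product is identifiable from
steady-state currents — so the scale is carried entirely by `N`.  Rates are
parameterised in log space with bounds [1e-2, 1e10] to keep positivity
across orders of magnitude.

The K+-site mutant scenario (`apply_mutant_scaling()`) divides `k23_0` by
1000 (or multiplies `k32` by 1000) and re-derives `k43_0` so the
reversibility identity still holds.  On the defaults this raises `K_K`
1000-fold (to within 0.1%; the identity-preserving re-derivation makes the
scaling only approximate at nonzero internal products) and *lowers* `K_H`
— reduced K+ binding backs the cycle up into the proton-bound state, so
less external H+ is needed for half-maximal turnover.  Whether the two
mutant encodings are exactly equivalent is not derivable from theory: the
package measures the discrepancy, and on the defaults the two
current–concentration curves at -120 mV agree within about 4%, which the
suite asserts at a 5% bound.

## Thermodynamic uptake limits

`channel_uptake_limit()` and `symport_uptake_limit()` compute the minimal
external K+ from which net uptake is possible: `K_in * 10^(V/s)` for an
uncoupled channel and `K_in * 10^(n_H * dpH) * 10^((1+n_H) V / s)` for an
n_H:1 symporter, with `s` the decadic Nernst slope.  The default slope is
60 mV per decade, which makes the canonical scenario (150 mM internal K+,
-180 mV, two pH units) come out at the round figures 150 uM, 1.5 nM, and
an advantage of exactly 1e5; the physically exact slope
`nernst_slope(T_K)` = 59.16 mV at 25 °C is available and gives 136 uM
instead.  `delta_pH` is defined as out minus in (negative when the bath is
more acidic).  A cross-module test verifies that the symport limit is
exactly the concentration at which the kinetic model's reversal potential
equals the holding voltage.

## The fitting layer

Peak-current dose-response curves are fitted with
`fit_michaelis_menten()` (Levenberg–Marquardt, `K_m` initialized at the
log-interpolated concentration nearest half the largest response) and
`fit_hill()` (free Hill coefficient, initialized at 1 so the fit nests the
Michaelis–Menten case).  Steady-state currents follow the bell-shaped
curve

$$I_{ss}([K]) = I_{max}\frac{[K]\,K_m}{([K]+K_m)^2} + I_s,$$

fitted with `K_m` held at the peak-fit value; since the model is then
linear in `(I_max, I_s)`, ordinary least squares is exact
(`fit_steady_state_bell()`).  The curve's maximum sits analytically at
`[K] = K_m` (`bell_argmax()`), which is why the concentration of maximal
steady-state current coincides with the peak-fit `K_m` — the package's
single headline number (28.3 uM for the wild type; the source text prints
that value with a mM unit in one place and ~28 uM elsewhere, which the
documentation treats as a unit typo rather than silently correcting the
number).

Fits are unweighted by default (optional per-point weights), responses are
magnitudes `|dI|`, and percent inactivation is
`100 * (dI_peak - dI_ss) / dI_peak`.  Trace features are extracted with
the baseline defined as the median current of the pre-step window and the
steady state as the mean over the final 5% of the pulse — the pulse end
rule made robust to sampling noise.

## What the synthetic generator emulates — and what it does not

`generate_dose_response()` draws
`response = model(conc) * (1 + cv * z) + additive_sd * z'` with seeded
standard normals: multiplicative noise across replicate "oocytes"
dominates real dose-response scatter.  `simulate_tevc_trace()` builds
concentration-step traces: per segment the current rises
mono-exponentially (`tau_act` = 0.7 s, putting the peak near 2 s) and
relaxes (`tau_inact` = 20 s, complete within a 120 s pulse) toward the
bell-curve steady-state level, on top of a leak current of the magnitude
measured in control oocytes (-85 +/- 7 nA).  The preset couples the
apparent `K_m` to pH through proton-site occupancy, so inactivation grows
both with concentration (2 mM >> K_m: near-complete) and with
alkalinisation (20 uM at pH 6.5 inactivates although the same
concentration at pH 4.5 does not).  The steady-state scale (1.2x the peak
scale) and offset (5% of the peak scale) were chosen once so the presets
reproduce that qualitative ladder.

The generator does **not** emulate capacitive transients, series
resistance, bath-electrode artefacts, per-oocyte expression drift within a
protocol, or the two time constants' possible dependence on voltage.
Passing round-trip tests therefore demonstrates correctness of the
estimators under the assumed noise structure, not robustness to every
artefact of real recordings.

## Numerical choices and problem sizes

* Occupancy oracle vs closed form: 50 randomized rate sets, 1e-9 relative.
* Half-saturation oracle: coarse log grid (0.25 decade) to bracket, then
  bisection to 1e-14; agreement with the closed forms asserted at 0.1%.
* Monte-Carlo estimator checks: 200 seeded datasets, CV 5%, 5 replicates
  at the eight standard test concentrations (10–2000 uM); median `K_m`
  bias below 5%.
* Traces are sampled at 10 Hz for 130 s (1300 points), enough to resolve
  `tau_act` while keeping the whole suite in a few seconds.
* Degenerate inputs (all-zero rates, zero concentrations in the reversal
  potential, non-positive peak in percent inactivation) raise classed
  errors rather than returning NaN.

## Known limitations

* The defaults are a calibrated stand-in for the original rate table; they
  reproduce the printed affinities, the saturating current and the
  qualitative voltage/mutant behaviour, but not necessarily every digit of
  the original simulated curves.
* The model is strictly steady state: pre-steady-state relaxations, and
  the inactivation process itself, are outside the cycle (traces emulate
  inactivation phenomenologically).
* Stoichiometries other than 1:1 and the original six-state scheme (from
  which this cycle is obtained by lumping the internal release states) are
  out of scope.
* Identifiability: with three calibration targets the structural rates are
  fixed by design choice, not estimated; a global identifiability analysis
  of all eight constants is deliberately not attempted.
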