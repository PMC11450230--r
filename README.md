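# hak5kin

Steady-state kinetics of high-affinity K+/H+ symport, for
electrophysiologists and modellers working on HAK/KUP/KT-family potassium
transporters expressed in *Xenopus* oocytes.

Plant roots scavenge micromolar potassium through transporters that couple
one K+ to one H+ per cycle.  Under two-electrode voltage clamp (TEVC) such
a transporter shows a characteristic phenotype: Michaelis–Menten K+
dose-response curves with micromolar `K_m`, proton-activated currents with
a steeply voltage-dependent apparent H+ affinity, inward rectification,
and a bell-shaped steady-state current caused by inactivation above `K_m`.
`hak5kin` packages the kinetic theory behind those observations together
with the fitting tools used on the recordings.

## The model

A four-state cycle — empty outward-facing carrier (C1), H+ bound (C2), H+
and K+ bound (C3), empty inward-facing carrier (C4) — with one
voltage-dependent step across a single symmetric Eyring barrier:

    k14 = k14_0 e^{FV/RT}      k41 = k41_0 e^{-FV/RT}
    k12 = k12_0 [H+]o          k23 = k23_0 [K+]o        k43 = k43_0 [H+]i [K+]i

Microscopic reversibility fixes one constant:
`k41_0 k12_0 k23_0 k34 = k14_0 k21 k32 k43_0`.  The steady state is solved
in closed form by the King–Altman method (sixteen directed spanning-tree
terms), giving the transported current

    I = 2 e N (k14 C1 - k41 C4)
      ∝ [H+]i[K+]i e^{FV/RT} - [H+]o[K+]o e^{-FV/RT}   (inward negative)

and, because the denominator is linear in each external concentration,
*exact* Michaelis–Menten reductions with closed-form `K_K`, `K_H` and
`I_max`.  An independent numeric null-space oracle cross-checks the
algebra throughout the test suite.

The companion layers provide the Nernst-type uptake limits of channel
vs. proton-coupled transport, the dose-response fitting used on TEVC
recordings (Michaelis–Menten, Hill, bell-shaped steady state, percent
inactivation), and a seeded synthetic-data generator for concentration-step
protocols.  See the vignette `vignettes/symport-kinetics.Rmd` for the full
account.

## Worked example

```r
library(hak5kin)

## Calibrated default rate constants (calibrated to printed wild-type
## observables -- not an author-supplied table)
p <- hak5_default_params()

## Inward current elicited by 20 uM K+ at -120 mV, pH 4.5
steady_state_current(p, conditions(V = -120, pH_out = 4.5, K_out = 20e-6))
#> Steady-state symport solution
#>   occupancies: C1=0.0008, C2=0.4887, C3=0.3474, C4=0.1631
#>   I = -159.564 nA (I+ = 0.176012, I- = -159.74)

## Apparent affinities at the holding potential
km_imax_potassium(p, V = -120, H_out = 10^-4.5)
#> Reduced Michaelis parameters (K+): K_K = 23.56 uM, I_max = -347.9 nA at -120 mV
km_proton(p, V = -120, K_out = 200e-6)
#> Reduced Michaelis parameters (H+): K_H = 4.81 uM, I_max = -358.6 nA at -120 mV

## Voltage dependence: K_K barely moves, K_H shifts ~460-fold,
## the saturating current grows with hyperpolarisation
voltage_scan(p, c(-150, -120, -90, -60))
#>   V_mV        K_K_M      I_Kmax_A        K_H_M
#> 1 -150 2.676058e-05 -4.333955e-07 5.376312e-07
#> 2 -120 2.356000e-05 -3.479128e-07 4.810000e-06
#> 3  -90 1.794690e-05 -1.390102e-07 3.952858e-05
#> 4  -60 1.626226e-05 -2.133114e-08 2.486515e-04

## Fit a noisy synthetic K+ dose-response (5 replicate oocytes, CV 5%)
d <- generate_dose_response(list(I_max = 1, K_m = 23.56e-6),
                            c(10, 20, 50, 100, 200, 500, 1000, 2000) * 1e-6,
                            noise_model(cv = 0.05, seed = 42),
                            n_replicates = 5)
fit_michaelis_menten(d)
#> Michaelis-Menten fit (converged)
#>   I_max      0.998961  (se 0.0109)
#>   K_m        2.3682e-05  (se 1.34e-06)
#>   residual norm 0.2645 on 40 points
```

The fitted `K_m` of 23.7 uM recovers the generating truth (23.56 uM)
within its standard error; the first two blocks show the calibrated model
reproducing the measured wild-type affinities exactly, and the voltage
scan shows the weak-vs-steep voltage dependence of the K+ and H+ binding
sites.

A command-line interface wraps the same functions:

```sh
RSCRIPT=$(Rscript -e 'cat(system.file("exec/hak5kin", package = "hak5kin"))')
Rscript "$RSCRIPT" limits --format text
# channel uptake limit : 0.00015 M
# symport uptake limit : 1.5e-09 M
# accumulation advantage: 100000
```

i.e. at 150 mM cytosolic K+ and -180 mV a K+ channel supports uptake only
above 150 uM external K+, while a 1:1 H+ symporter with a 2-pH-unit
gradient works down to 1.5 nM — a 100000-fold advantage.  Subcommands:
`limits`, `calibrate`, `scan-voltage`, `generate-dr`, `fit`,
`simulate-trace` (see `run_cli(character(0))` for usage).

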