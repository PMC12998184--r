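# gutnitro

Quantifies bacterial nitrite and nitrate detoxification in the human large
intestine. Gut bacteria reduce dietary and recirculated nitrite
(NO₂⁻) to ammonium or NO; that collective reductase activity keeps colonic
nitrite below the levels at which it nitrosates amines (forming carcinogenic
N-nitroso compounds) and inhibits sensitive commensals. `gutnitro` is for
microbiologists and microbiome researchers who run incubation assays and
want a reproducible path from raw plate-reader time series to specific
activities and whole-organ capacity estimates.

## What it computes

**Specific activity from depletion curves.** For an incubation series
(time, OD600, analyte concentration, pH), the pipeline fits a functional
form to the concentration course C(t) (model family: constant, linear,
exponential-plus-offset, logistic decline; AICc selection; monotone-spline
fallback), differentiates it analytically, pairs the rate −dC/dt with
dry-weight biomass X_DW = OD₆₀₀ × β (β = 0.36 g L⁻¹ OD⁻¹ by default), and
takes the origin-constrained slope over the *initial linear portion* of
rate versus biomass:

    a  =  slope of (−dC/dt) [µmol L⁻¹ h⁻¹]  vs  X_DW [g L⁻¹]
       =  specific activity in µmol g_DW⁻¹ h⁻¹

Readings below the 10 µM detection limit are censored (excluded, never
zeroed), abiotic losses (instantaneous cysteine scavenging; pH-dependent
first-order decay) are corrected, and depletion uncorrelated with biomass
is reported as "< threshold" instead of as activity.

**Whole-colon extrapolation.** Measured activities scale to organ capacity
through literature constants (3.23×10¹¹ cells per g dry stool, 2.52×10⁻¹³ g
per cell, 400 mL stool at 1.04 g mL⁻¹ and 75 % water → 104 g dry stool):
cells/g → biomass/g → dry-stool activity → total µmol h⁻¹, plus bolus
detoxification times and abundance back-estimation.

**Growth-inhibition phenotyping.** Lag, doubling time and maximum OD per
nitrite dose, classified as insensitive / lag extension / capacity loss /
complete inhibition above a threshold concentration.

**Synthetic data.** Every input (growth curves, depletion courses,
calibration standards, counting experiments, dose-response plates) can be
generated with known ground truth and seed-deterministic noise, so the
whole pipeline is validated by parameter recovery.

## Worked example

A resting-cell community assay (OD600 = 8, i.e. 2.88 g_DW L⁻¹) spiked with
a nominal 150 µM nitrite (effective 100 µM after cysteine scavenging),
simulated at a true activity of 70 µmol g_DW⁻¹ h⁻¹ with 2 µM read noise,
then analysed blind:

```r
library(gutnitro)

g   <- data.frame(time_h = seq(0, 1.5, 0.05), od600 = 8)
sim <- simulate_depletion(g, consumption_params(70, km = 0),
                          abiotic_params(), c_nominal = 150,
                          noise = noise_spec(conc_sd = 2, seed = 42))
assay_specific_activity(sim$series)
#> <kinetics_result> nitrite: 68.8 umol/gDW/h (se 0, linear fit, window 9/9)
```

The estimate (68.8) recovers the generating truth (70) within 2 %; the
window report says all 9 pre-depletion points were proportional to
biomass. Scaling a strong single-species reducer (specific activity
10 966 µmol g_DW⁻¹ h⁻¹ at 0.8 % abundance) to the whole colon:

```r
ec <- activity_chain(taxon_profile("Escherichia coli", abundance = 0.008,
                                   specific_activity = 10966))
ec
#> <colon_activity> Escherichia coli
#>   cells / g dry stool      : 2.58e+09
#>   biomass (gDW/g dry stool): 0.000651
#>   dry-stool activity       : 7.14 umol/g/h
#>   colon dry mass           : 104 g
#>   total colonic activity   : 743 umol/h

detox_time(bolus_amount(50, 400), ec$total_activity)
#> [1] 1.615871
```

A 50 µM nitrite bolus in 400 mL of stool (20 µmol) would be cleared by
this one taxon in about 1.6 minutes — the quantitative core of the argument
that colonic nitrite should sit below the assay's 10 µM detection limit.

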