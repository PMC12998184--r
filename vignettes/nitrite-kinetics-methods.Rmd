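---
title: "Methods: quantifying nitrite detoxification by gut bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying nitrite detoxification by gut bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutnitro)
```

## The problem

Dietary and endogenously recycled nitrate and nitrite reach the large
intestine, where nitrite is both a precursor of carcinogenic N-nitroso
compounds and an inhibitor of several beneficial anaerobes. Many gut
bacteria reduce nitrite enzymatically (to ammonium or NO), so the
community's collective reductase activity sets the steady-state nitrite
level of the colon. `gutnitro` implements the quantitative workflow needed
to measure that activity in incubation assays and to scale it up to the
whole organ:

1. calibrate the colorimetric nitrite assay and censor readings below its
   detection limit;
2. correct measured time series for abiotic (non-bacterial) nitrite losses;
3. turn substrate-depletion curves into **specific activities** in
   µmol g$_{DW}^{-1}$ h$^{-1}$;
4. convert cell counts and dry weights into the biomass factors that the
   normalization needs;
5. extrapolate specific activities to whole-colon detoxification capacity;
6. classify how nitrite inhibits the growth of sensitive species.

Because the raw plate-reader data behind any particular study are not
needed to validate the *procedure*, a synthetic-data module generates every
input with known ground truth, and the test suite checks that each stage
recovers that truth.

## The kinetic model

### Growth

Growth curves are modelled as a lag phase followed by a logistic rise:
for $t \le \lambda$ (lag, h) the culture sits at its inoculation density
$N_0$ (OD600); afterwards

$$N(t) = \frac{K N_0 e^{r(t-\lambda)}}{K - N_0 + N_0 e^{r(t-\lambda)}},
\qquad r = \frac{\mu_{max}}{1 - N_0/K},$$

with carrying capacity $K$ (maximum OD). The rate constant is scaled so
that the *maximum specific growth rate* — the quantity that defines the
doubling time $t_d = \ln 2 / \mu_{max}$ — equals $\mu_{max}$ exactly, which
keeps simulator truth directly comparable with what a log-linear fit of a
growth curve estimates. This three-parameter-plus-lag form was chosen over
richer families (Gompertz, Richards) because lag, doubling time and maximum
OD are precisely the parameters reported for plate growth experiments, and
a parsimonious model keeps recovery tests interpretable.

### Substrate depletion

Nitrite (or nitrate) consumption couples enzymatic degradation,
proportional to dry-weight biomass, with pH-dependent chemical decay:

$$\frac{dC}{dt} = -a \, X_{DW}(t)\, \frac{C}{k_m + C} - k_{pH}(t)\, C,
\qquad X_{DW}(t) = \mathrm{OD}(t) \times \beta,$$

where $a$ is the specific activity (µmol g$_{DW}^{-1}$ h$^{-1}$),
$\beta$ the biomass conversion (g L$^{-1}$ per OD unit, default 0.36, the
community average of the bundled calibration table), and $k_m$ a
half-saturation constant. $k_m$ is a *simulator construct*: the true
functional form of microbial nitrite uptake is not established, and the
default $k_m = 20$ µM is chosen only so that one knob reproduces both the
near-linear early decline seen in growing cultures and the exponential
tails reported for fast degraders. $k_m$ is never fitted from data — the
measured quantity is always the initial rate per biomass.

The ODE is integrated with an adaptive explicit Runge-Kutta scheme
(`deSolve::ode`, method `ode45`) with the step size capped at 0.01 h:
stiffness is mild at these rates and exact reproducibility across
platforms matters more than speed.

### Abiotic corrections

Two chemical sinks are separated deliberately:

* **Instantaneous cysteine scavenging.** The reducing agent consumes part
  of the nitrite spike within seconds. The default magnitude, 100/3 µM per
  mM cysteine, is anchored so that the standard assay condition (nominal
  150 µM spike, 1.5 mM cysteine) yields an effective 100 µM starting
  concentration. The 24 h dose–response trend is shallower
  (≈ 17.5 µM/mM); users analysing long-horizon cell-free data should
  calibrate `cysteine_loss_per_mM` from that trend instead, as the
  long-horizon test does.
* **pH-dependent first-order decay.** Above pH 5.8 chemical loss plateaus
  at roughly 10 % over 24 h, i.e. a first-order rate of $-\ln(0.9)/24
  \approx 0.0044$ h$^{-1}$, which is the default table. Below pH 5.8
  nitrite is protonated to HNO$_2$/NO$^+$ and scavenged much faster, but
  the rates are medium-specific, so the package requires a user-supplied
  table there rather than inventing one.

`subtract_abiotic()` inverts the first-order channel by multiplying each
reading by $\exp\!\big(\int_0^t k_{pH}(\tau)d\tau\big)$ (trapezoidal
cumulative integral over the recorded pH trace), so that a cell-free
control series is restored to a constant.

## The specific-activity procedure

The estimator mirrors the classical workflow — fit a functional equation to
$C(t)$, differentiate it, and read the activity off the initial linear
portion of rate versus biomass — with two automations:

* **Model selection.** Four candidate forms (constant, linear,
  exponential-plus-offset, logistic decline) are fitted to the uncensored
  readings and compared by small-sample-corrected AIC; candidates whose
  fitted curve is not monotone non-increasing over the data range are
  discarded, and a monotone (Hyman) cubic spline after an antitonic
  projection serves as fallback. Analytic derivatives of the winning form
  give the rate series (validated against central finite differences to
  relative $10^{-6}$ in the tests).
* **Window search.** The "initial linear portion" is the longest prefix
  (minimum 3 points, configurable) of the rate-versus-$X_{DW}$ pairs whose
  through-origin coefficient of determination is at least 0.95
  (configurable). The specific activity is the origin-constrained slope
  within that window: rate in µM h$^{-1}$ ≡ µmol L$^{-1}$ h$^{-1}$ divided
  by biomass in g L$^{-1}$ lands directly in µmol g$_{DW}^{-1}$ h$^{-1}$.
  Using the whole window rather than a single-point ratio buys robustness
  against individual noisy timepoints.

Readings below the detection limit (default 10 µM, the assay's stated
sensitivity) are excluded from fitting, and the first censored timepoint
defines a terminal time after which rates are not evaluated — censored
values propagate as an explicit state, never as zeros.

### Attribution guard

Some species show a slight linear nitrite decline only in stationary
phase, uncorrelated with optical density — cell lysis releasing reactive
cytoplasmic compounds, not enzymatic activity. The pipeline guards against
reporting such artifacts as activity: `classify_below_threshold()` reports
"< threshold" not only when the upper confidence bound falls below the
reporting threshold, but also when no proportional window exists or when
the proportional window covers less than 25 % of the pre-depletion assay.
In the artifact scenario the rate is flat while biomass rises tenfold, so
the proportional prefix is confined to the lag phase and the guard fires;
in genuine assays (resting cells at constant OD, or growth-coupled
depletion) the window spans most of the assay and the guard stays silent.

## Biomass calibration

Counting-chamber arithmetic uses the square volume
$0.0025\ \mathrm{mm^2} \times 0.02\ \mathrm{mm} = 5\times10^{-8}$ mL, so 20
cells per square in an undiluted sample are $4\times10^8$ cells mL$^{-1}$.
Per-cell dry mass is the *origin-constrained* regression slope of dry
weight on cell number — zero cells imply zero mass, which settles the
intercept the protocol leaves unstated. Duplicate 24 h/48 h drying
measurements are averaged and flagged when they disagree by more than 5 %.
The bundled reference table of fourteen gut species averages to
$2.52\times10^{-13}$ g per cell (one species lacks a dry-weight
determination and is excluded from averages, mirroring the reference
layout).

## Whole-colon extrapolation

The extrapolation chain multiplies through a handful of literature
constants (defaults in `stool_physiology()`): $3.23\times10^{11}$ bacteria
per g dry stool, 400 mL colonic stool content, wet density 1.04 g mL$^{-1}$,
75 % water, $2.52\times10^{-13}$ g per cell. For a taxon at abundance $f$
with specific activity $a$:

$$\text{cells/g}_{ds} = f \cdot 3.23\times10^{11},\quad
\text{biomass/g}_{ds} = \text{cells} \times m_{cell},\quad
A_{ds} = a \times \text{biomass/g}_{ds},$$
$$M_{dry} = 400 \times 1.04 \times 0.25 = 104\ \mathrm{g},\qquad
A_{tot} = A_{ds} \times M_{dry}.$$

A nitrite bolus of 50 µM in 400 mL holds 20 µmol; at a total activity of
742 µmol h$^{-1}$ the detoxification time is $20/742 \times 60 \approx
1.6$ min. The detox time deliberately assumes zero-order consumption at
the measured rate: it is a capacity argument, not a dynamic model.
Abundance is interpreted as a fraction of cell counts *and*, through the
shared average cell mass, of biomass — the single community-average cell
mass equates the two. Mixture predictions renormalize abundance weights
over the included taxa, because a defined strain mixture contains only
those strains.

## Growth-inhibition phenotyping

Per growth curve, the maximum specific growth rate is the steepest slope
of $\log(\mathrm{OD})$ over a sliding window (default 5 points), the lag is
the tangent-intercept (where that steepest log-linear fit crosses the
initial log-OD), and the maximum OD is the peak of a running-median-smoothed
curve; curves rising less than 0.05 OD are flagged as no growth. Dose
profiles are classified against the 0 µM reference with a 25 % relative
change threshold and a fixed precedence:

`complete_inhibition_above_threshold` > `capacity_loss` > `lag_extension` >
`insensitive`.

The 25 % default separates the three archetypal behaviours cleanly while
tolerating their reported replicate scatter; precedence resolves mixed
signatures deterministically (a strain whose capacity collapses *and* that
stops growing entirely above some dose is reported by the stronger, fully
inhibited signature, keyed to the lowest no-growth concentration).

## What the synthetic data do and do not show

The generators emulate lag/exponential/stationary growth, biomass-coupled
Michaelis–Menten depletion, instantaneous cysteine scavenging, pH-dependent
first-order decay, Gaussian measurement noise and the 10 µM detection
limit, with full seed determinism. Deliberately absent are: medium
acidification feeding back on the decay rate, strain interactions in
mixtures, plate-edge and drift artifacts, and heteroscedastic assay noise.
Passing recovery tests therefore show that the *estimators* are unbiased
and robust at realistic noise levels under the stated generating laws —
not that any particular laboratory's raw data would be reproduced.

Study conditions used in the validation runs (chosen once, as the
package's own design):

* **Recovery grid.** Resting-cell simulations at specific activities 10,
  100, 1000 and 10 000 µmol g$_{DW}^{-1}$ h$^{-1}$, effective 100 µM
  nitrite, 2 µM concentration noise, 20 seeds per level. Cell density is
  scaled to each activity (so the zero-order depletion rate is ~40 µM/h
  and the assay resolves 20+ pre-depletion samples at 0.1 h spacing), as a
  bench scientist would dilute a fast degrader. These runs use $k_m = 0$:
  the resting-cell assays being emulated deplete nitrite essentially
  linearly, and the initial-rate estimand equals the generating $a$ only
  for a zero-order law — with $k_m > 0$ the initial rate is
  $a\,C_0/(k_m + C_0)$ by construction, a property of the assay design,
  not an estimator defect. Median recovery error is ~1 %, well inside the
  10 % requirement.
* **Phenotyping.** The three archetypes at their reported effect sizes,
  doses 0–1000 µM, 3 % OD noise, 20 seeds, sampled every 0.25 h for 48 h.
  The 48 h horizon is what lets the slowest curve (20 h lag, 1.74 h
  doubling at 1 mM) reach its true plateau; at 24 h its maximum OD would
  be undersampled and lag extension would masquerade as capacity loss.
  Classification accuracy is 100 % across seeds.

## Numerical choices and degenerate inputs

* ODE: `ode45`, `hmax = 0.01` h, `rtol = atol = 1e-8`.
* With $k_m = 0$ the depletion law switches off exactly at $C = 0$; the
  solver's capped step makes the kink harmless and concentrations are
  clamped at zero.
* Model selection ties go to the fewer-parameter form via the AICc
  penalty; nonlinear candidates that fail to converge are simply dropped.
* Through-origin $R^2$ is the uncentered $1 - \sum r_i^2 / \sum y_i^2$,
  defined as 1 when all rates are numerically zero (so a flat, zero-rate
  assay is "perfectly proportional" with slope 0 rather than undefined).
* Calibration fits are unweighted least squares; degenerate standards
  (fewer than 3 distinct levels, or zero absorbance variance) are errors,
  a missing blank is a warning.
* pH outside [3, 9] is refused; pH below the decay table's span is an
  error rather than an extrapolation.
* Fully scavenged spikes (effective $C_0 \le 0$) raise an error
  identifying the input as unusable rather than returning an empty series.

## Known limitations

* The cysteine channel is two anchored coefficients, not a mechanistic
  thiol–nitrite model; the instantaneous and 24 h anchors are mutually
  inconsistent at high cysteine, and the package sides with the
  instantaneous anchor for initial-concentration correction.
* Acidic-pH decay must be user-supplied; there is no default below pH 5.8.
* Specific activities from growing cultures with saturating kinetics
  estimate the realized initial rate per biomass, which is below the
  zero-order asymptote whenever $C_0$ is not ≫ $k_m$.
* The colon model is a single well-mixed compartment: no absorption,
  secretion, transit or enterosalivary recirculation, and no nitrosamine
  chemistry.
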