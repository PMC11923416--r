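---
title: "Time-integrated hydrogen isotope signal screening in conifer needles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-integrated hydrogen isotope signal screening in conifer needles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoneedle)
```

## The problem

The hydrogen isotope composition (δ²H, ‰ VSMOW) of needle *n*-alkanes,
water-soluble carbohydrates (WSC) and starch records a mixture of
hydrological information (the δ²H of source water and of evaporatively
enriched leaf water) and physiological information (gas exchange during the
period over which each compound pool turned over). Because the compound
pools integrate over very different time scales — days for sugars and
transitory starch, weeks for leaf-wax alkanes — a measured compound value
must be compared against *time-integrated* environmental drivers, not
instantaneous ones, before any signal can be claimed.

`isoneedle` implements that comparison chain end to end: half-hourly
forcings → leaf conductance → modeled source-water and needle-water δ²H →
compound-level isotope corrections → daytime-filtered window averages of
every candidate driver → a Spearman/Holm correlation screen over all
driver × window combinations → random-intercept mixed-model confirmation of
the prevailing signals. A synthetic-data generator with *planted* ground
truth makes every stage testable by recovery: we know which driver, at
which integration window, with which slope, generated the data, and we can
ask whether the screen finds it.

## Water isotope models

**Source water.** The rooting zone is a single well-mixed reservoir
(default capacity 150 mm). Daily precipitation mixes in by exact isotope
mass balance; uptake and drainage are non-fractionating and leave the
composition unchanged; overflow leaves at the post-mixing composition. The
model's purpose is to provide a continuous, slowly varying δ²H_source for
gap-filling; soil layering, Richards-equation physics and soil evaporation
are deliberately out of scope. The daily series starts at 01 April: winter
uptake is too uncertain to initialise earlier, so the reservoir simply
starts full at a configurable composition (default −90 ‰, a plausible
boreal winter recharge value, not a measurement). Any model-minus-
measurement bias on days with twig-water measurements is reported by
`blend_with_measurements()`, never silently corrected.

**Needle water.** Evaporative-site enrichment follows the Craig–Gordon
form Δₑ = ε⁺ + ε_k + (Δᵥ − ε_k)·e_a/e_i, with

* ε⁺ from the Horita & Wesolowski (1994) liquid–vapor ²H polynomial,
  pinned by coefficient in `equilibrium_fractionation()` and
  tolerance-tested against its own coefficients;
* ε_k from the conductance-weighted stomatal (25 ‰) / boundary-layer
  (17 ‰) kinetic form, with boundary-layer conductance defaulting to
  2.4 mol m⁻² s⁻¹, the midpoint of the published *Pinus* range
  (2–2.84 mol m⁻² s⁻¹);
* Δᵥ, the vapor disequilibrium, computed from δ²H_vapor and δ²H_source by
  exact ratio algebra (`delta_above_source()`), never by subtraction.

Bulk-lamina corrections: the Péclet correction Δ_L = Δₑ(1 − e^−℘)/℘ with
℘ = E·L_eff/(C·D) (series expansion below ℘ = 10⁻⁶ to avoid cancellation),
or the two-pool correction Δ_L = (1 − φ)Δₑ. The two are exactly equivalent
when φ = 1 − (1 − e^−℘)/℘, which the tests assert. The headline continuous
series uses the Péclet-corrected steady state.

The nonsteady-state variant integrates dΔ_Ln/dt = (Δ_Ls − Δ_Ln)/τ with
τ = W·α⁺·α_k/(g_t·w_i), explicit Euler with sub-stepping whenever the
30-min step exceeds τ/2 (and a direct jump to steady state when more than
10⁴ sub-steps would be needed — the stiff limit). When g_t = 0 overnight, τ
is infinite and enrichment is held constant: physically, the leaf stops
exchanging water vapor. This is why nonsteady-state *day means* can sit
well above steady-state day means under diurnal forcing, while the two
agree within 2 ‰ when the forcing varies slowly relative to τ.

Defaults L_eff = 0.02 m, W = 12 mol m⁻², φ = 0.2 are package defaults in
the typical literature range, exposed in every signature; none is a
field-calibrated value.

**A single saturation-vapor-pressure formula** (Magnus, Alduchov &
Eskridge 1996: 0.61094·exp(17.625·T/(T + 243.04)) kPa) is used everywhere —
generator, conductance, leaf-water model — so e_i and e_a are mutually
consistent by construction. Leaf temperature defaults to air temperature
(adequate for well-coupled conifer shoots; an additive offset is
available).

## Gas exchange

Total conductance is inverted from transpiration,
g_t = E(p − ė)/(e_i − e_a) with ė = (e_i + e_a)/2. For g_t < 0.3 mol m⁻²
s⁻¹ and boundary-layer conductance in the *Pinus* range, removing the
boundary-layer term changes the result by under 15 % (the tests assert
this on a grid), which is why g_t serves as a stomatal-conductance proxy.
Records implying negative conductance (e_a > e_i with positive E) are
flagged invalid rather than propagated. The assimilation filter removes
fluxes at or below a detection threshold (default 0.1 in column units;
published unit conventions for this cutoff are inconsistent, so the value
is configuration, not a hard-coded conversion). Gap-filling is a pluggable
interface — an intercept-only filler and a linear light/VPD/temperature
regression are registered — that never alters observed records and reports
R² and RMSE diagnostics.

## Compound corrections

Four exact-algebra operations, each with its forward companion and
round-trip tested to 10⁻¹⁰ on a thousand random fixtures:

* **Nonexchangeable H** from two-water equilibration: the measured value is
  a mixture m = f·x(water) + (1 − f)·δ²H_ne with x(water) =
  ε_exch + δ_water(1 + ε_exch/1000); two waters give a closed-form 2×2
  solution. ε_exch defaults to 80 ‰ (typical carbohydrate hydroxyl
  enrichment; package default). Sugar-like fixtures with f drawn in
  0.34–0.38 are recovered inside that band.
* **α-amylase unmixing** for starch: (δ_mix − w·δ_amylase)/(1 − w), with
  the concentration corrected by the same mass fraction.
* **Abundance-weighted alkane mean** over *n*-C25/27/29 (concentration
  weighting; peak-area weighting would be an alternative the data do not
  distinguish here).
* **ε_bio inversion**: δ²H_n-water = (δ²H_alkane − ε_bio)/(1 + ε_bio/1000),
  with defaults mean −156 ‰, minimum −133 ‰, maximum −192 ‰ from the
  conifer leaf-wax literature.

## Time integration and screening

Each driver is filtered to the 09:00–15:00 daytime window — implemented
half-open [09:00, 15:00) so boundary half-hours are counted once — and
averaged over windows *ending on the sampling date*: a 1-day window is the
sampling day, a 2-day window adds the preceding day, and week windows
follow the same rule with week 0 meaning the sampling day alone. Daily
drivers (modeled δ²H_source) skip the daytime filter, having no sub-daily
structure. Windows reaching before 01 April are clipped at that floor and
flagged `truncated` — early-season events keep their shortened windows
rather than being dropped. Windows with under 25 % of expected half-hours
are flagged `low_coverage`, also not dropped; the choice to flag rather
than discard is ours, made because desk-scale users should see their
coverage problems.

The screen computes Spearman rank correlations (midranks under ties; the
p-value is exact by full permutation for n ≤ 7 — valid under ties, unlike
classical null tables — and the t approximation otherwise) between every
response and every driver × window cell, then applies a Holm step-down
correction *within families*. The default family is one response × cohort
× driver across its windows, because the multiplicity arises from trying
many integration lengths of the same driver; a pooled `"global"` family is
available for users who want familywise control across drivers too.
Significant cells are ranked by |ρ|, and all cells within 0.04 of the
leader are reported as co-leaders — rank differences that small are not
interpretable.

Confirmation uses REML random-intercept models (`lme4`). Tree identity and
sampling date are the default random intercepts; alkane responses
typically need the more parsimonious tree-only structure. The summaries

* R²(M) = σ²_f/(σ²_f + σ²_r + σ²_e),
* R²(C) = (σ²_f + σ²_r)/(σ²_f + σ²_r + σ²_e),
* ICC = σ²_r/(σ²_r + σ²_e)

are computed in-package from the extracted variance components, with σ²_f
the variance of the fixed-effect fitted values; the tests re-derive each
from the reported components and assert the identities exactly. Singular
fits are flagged, with the offending component floored at zero.

## What the synthetic generator emulates — and what it does not

The generator produces a 01 April – 15 October boreal season at 30-min
resolution: an annual temperature cosine (minimum mid-January, so the
minimum of the simulated span falls at its early-April start; maximum
mid-July), a diurnal sine peaking at 15:00, a day-scale synoptic AR(1)
anomaly (persistence 0.7/day), and 30-min AR(1) noise with coefficient 0.8.
Relative humidity is anti-phase with the diurnal temperature cycle,
increases on overcast and rainy days, and is clipped to [20, 100] %.
Cloudiness is its own day-scale AR(1) latent process squashed to
[0.35, 1]: it lowers assimilation and conductance and raises humidity.
This day-scale weather variability is essential to the package's own
recovery tests — without it, window means of a driver would differ only
through the smooth seasonal trend and adjacent integration windows would
be indistinguishable. Stomatal conductance is down-regulated by vapor
pressure deficit, and assimilation carries an independent day-scale
capacity anomaly, so A_n and g_t are correlated but not rank-identical —
otherwise "which driver carries the signal" would be ill-posed.
Precipitation events start as a Poisson process (rate 0.01 per half-hour,
mean depth 2 mm); precipitation δ²H follows a seasonal sine from −130 ‰
(winter) to −55 ‰ (summer) — plausible boreal values, not site data — and
vapor is in isotopic equilibrium with precipitation at air temperature.

Sampling emulates the study design: five trees, approximately biweekly,
one-year-old needles (1N) sampled 30 April – 8 August and current-year
needles (0N) 12 June – 11 October. The planted response is strictly linear
in the true windowed driver with Gaussian tree intercepts and residuals.

What passing recovery tests therefore *do not* show: the generator has no
radiation field (a fixed 04:00–18:00 photoperiod stands in for solar
geometry), no humidity–temperature covariance beyond the diurnal/synoptic
structure, no needle ontogeny (real 0N needles grow during the season),
no compound-pool turnover dynamics (the planted linear response is an
idealisation of what is really a convolution over pool residence times),
and no measurement error structure beyond i.i.d. Gaussian noise. Recovery
on synthetic data validates the *machinery* — windowing, ranking,
multiplicity control, variance partitioning — not the biology.

## Frozen study conditions for the recovery experiments

Two scenarios, fixed once:

* **Mixed-model recovery** uses the default planted signal — A_n at a
  3-day window, slope 17 ‰ per μmol m⁻² s⁻¹, tree SD 3 ‰, residual SD 8 ‰
  (ICC ≈ 0.12) — magnitudes chosen to mirror a strong sugar–assimilation
  signal in the cohort design. The 95 % Wald interval on the slope must
  cover the planted value in at least 90 of 100 seeds.
* **Window recovery** uses a strong, low-noise planted signal (RH at a
  3-day window, slope 2 ‰ per %, tree and residual SD 1 ‰) on a
  full-season biweekly schedule (12 dates × 5 trees). Window
  identification does not need the cohort split, and more sampling dates
  give the rank statistics more information to separate adjacent windows,
  which differ only in one day of weather. The planted (driver, window)
  must be the grid argmax with the correct sign in at least 90 of 100
  seeds.

A null simulation (pure-noise responses, 100 seeds) checks that the
fraction of Holm families with any adjusted p below 0.05 stays at or below
0.07.

Problem sizes throughout — a single season of half-hourly data, 40–85
events, 100-seed recovery loops — are desk-scale choices that keep the
whole suite runnable in minutes while leaving the statistics
well-determined.

## Numerical choices and degenerate inputs

* Half-open daytime interval [09:00, 15:00): every half-hour is counted
  exactly once.
* Window means are pooled means over half-hours (missing values excluded
  from numerator and denominator), computed from per-day daytime sums so a
  (k+1)-day mean is exactly a convex combination of the k-day mean and the
  added day.
* Péclet damping switches to its series expansion below ℘ = 10⁻⁶.
* The nonsteady-state integrator holds enrichment constant over steps with
  zero conductance, sub-steps when Δt > τ/2, and jumps to steady state in
  the stiff limit.
* Reservoir demand exceeding available water floors storage at a
  configurable minimum and flags the event.
* Spearman is undefined for constant margins (flagged), and Holm is
  order-invariant (asserted over all 720 orderings of six p-values).
* All timestamps are fixed-offset UTC+2; no daylight-saving transitions
  exist in the synthetic calendar.

## Known limitations

The reservoir's capacity and drainage rule are deliberately simple
configuration, not calibrated soil physics; late-season source-water bias
against measurements is reported, not corrected. The Péclet effective path
length, leaf water content and two-pool fraction are order-of-magnitude
defaults. The screen's exact permutation p-values stop at n = 7 for cost;
beyond that the t approximation is used. No δ¹⁸O channel, no within-leaf
spatial models, no lag structures other than windows ending on the
sampling date.
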