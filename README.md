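# isoneedle

Time-integrated hydrogen isotope signal screening for conifer needle
compounds.

## What problem this solves

The δ²H of needle *n*-alkanes, water-soluble carbohydrates (WSC) and
starch is read both as a hydrological archive (leaf and source water δ²H)
and as a physiological recorder (gas exchange). But each compound pool
integrates its environment over a different horizon — roughly a day for
transitory starch, days for sugars, weeks for leaf-wax alkanes — so a
measured compound value must be compared with *time-integrated* drivers.
`isoneedle` is for isotope ecophysiologists who want that comparison chain
as tested, reusable code rather than a one-off analysis script:

* **Water isotope models** — a mass-balance rooting-zone reservoir for
  continuous δ²H_source, and Craig–Gordon needle-water enrichment
  Δₑ = ε⁺ + ε_k + (Δᵥ − ε_k)·e_a/e_i with Péclet
  (Δ_L = Δₑ(1 − e^−℘)/℘, ℘ = E·L/(C·D)), two-pool (Δ_L = (1 − φ)Δₑ) and
  nonsteady-state (dΔ_Ln/dt = (Δ_Ls − Δ_Ln)/τ, τ = W·α⁺α_k/(g_t·w_i))
  corrections.
* **Gas exchange** — total conductance g_t = E(p − ė)/(e_i − e_a) from
  transpiration, flux filtering, pluggable gap-filling.
* **Compound corrections** — nonexchangeable-H solution from two-water
  equilibration, α-amylase unmixing for starch, abundance-weighted alkane
  means, and ε_bio inversion
  δ²H_n-water = (δ²H_alkane − ε_bio)/(1 + ε_bio/1000).
* **Screening** — daytime-filtered (09:00–15:00) window means of every
  driver for windows of 1–5 days or 0–10 weeks ending on each sampling
  date; Spearman rank correlations over the full driver × window grid with
  Holm familywise correction; random-intercept mixed models (REML, `lme4`)
  reporting slope, marginal/conditional R² and ICC.
* **Synthetic data** — a boreal growing-season generator with planted
  ground-truth signals, so every downstream stage is testable by recovery.

## Worked example

```r
library(isoneedle)
pl <- run_pipeline(run_config(seed = 7))
print(pl$selection[1:3, c("driver", "window", "rho", "p_adj")])
#>   driver window       rho        p_adj
#> 1    A_n      4 0.9059141 5.963239e-17
#> 2    A_n      3 0.9045887 6.357662e-17
#> 3    A_n      1 0.8999497 1.261809e-16
print(pl$lmm)
#> Mixed model: d2H_WSC ~ pred + (1 | tree) + (1 | date)
#>   slope = 16.95 +/- 1.36   intercept = -248.81 +/- 5.73   n = 45
#>   R2(M) = 0.85   R2(C) = 0.88   ICC = 0.19
```

The default configuration plants a sugar-δ²H response to net assimilation
integrated over 3 days (slope 17 ‰ per μmol m⁻² s⁻¹) into synthetic
events from five trees sampled biweekly. The screen ranks the assimilation
windows at the top of the correlation grid (ρ ≈ 0.9, windows 2–5 days are
co-leaders within the 0.04 tie band — adjacent windows share most of their
weather), and the confirmation mixed model recovers the planted slope
(16.95 ± 1.36) with the variance split between fixed effect (R²(M) = 0.85),
tree/date intercepts (R²(C) − R²(M)) and residual noise. Exact printed
values vary slightly with the seed.

Individual stages are plain functions:

```r
total_conductance(0.002, 100, 2, 1)   # 0.197 mol m-2 s-1
craig_gordon(-80, 74, 25, 0.6)        # 36 permil evaporative-site enrichment
invert_epsilon_bio(-192.5, -156)      # -43.25 permil needle water from alkanes
```

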