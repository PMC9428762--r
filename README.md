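# heelpad

Viscoelastic material properties of the plantar heel pad, estimated from
synchronized stance-phase recordings of pad thickness and heel–ground
contact force.

The heel fat pad cushions every heel strike; diseases such as type II
diabetes thin it, stiffen it and — most importantly for ulcer risk —
degrade its viscous, shock-absorbing behaviour. Studies that quantify this
measure, per step: pad thickness per frame (fluoroscopy) and contact
force/area per frame (pressure plate), both at 50 Hz. `heelpad` implements
the analysis downstream of those channels, for biomechanics researchers and
methodologists who want a tested, reproducible reference pipeline:

* **Per-step derivation** — initial-contact detection, primary thickness
  h₀, compressive strain ε = (h₀ − d)/h₀, stress σ = 10·F/A (kPa), strain
  rate by finite differences, loading/unloading split, peak point.
* **Model fit** — the modified Kelvin–Voigt model

  σ = E·ε + η·ε·ε̇

  (linear elastic element in parallel with a nonlinear viscous element;
  compression positive) fitted by ordinary least squares with no intercept,
  giving the Young's modulus E (kPa) and viscous modulus η (kPa·s).
* **Hysteresis energetics** — trapezoidal loop areas and the energy
  dissipation ratio, EDR = 100 · (enclosed loop area)/(area under loading
  branch) %.
* **Synthetic-stance generator** — forward simulation of recordings from
  known (E, η, h₀) with configurable strain trajectory, contact-area model
  and channel noise, plus a cohort generator (groups × subjects × legs ×
  loading statuses with within-subject correlation) so the whole pipeline
  is testable without any in vivo data.
* **Cohort statistics** — normality-routed comparisons (Student/Welch t,
  Wilcoxon, paired variants; ANOVA / Brown–Forsythe / Kruskal–Wallis with
  SNK-q / Tamhane T2 / Dunn post hoc), summary-statistic t tests, Pearson
  correlation matrices with significance tiers, and `mean±SD` vs
  `median (range)` summaries.

Everything is tibble-first and pipe-friendly; fitted models support broom's
`tidy()`/`glance()`, and result types have `autoplot()` methods. A thin CLI
(`inst/cli/heelpad`) exposes `simulate`, `extract`, `fit`, `compare`,
`correlate` and `report` subcommands over CSV/XML file dialects.

## Worked example

Simulate one noise-free step from known parameters and recover them:

```r
library(heelpad)

gait <- gait_params(peak_strain_target = 0.52,
                    noise_sd_thickness = 0, noise_sd_force = 0)
rec <- simulate_stance(kv_params(E = 265.5, eta = 66.59, h0 = 14.85), gait)
extract_properties(rec)
#>   primary_thickness_mm peak_strain_pct peak_stress_kpa youngs_modulus_kpa
#> 1                14.85           51.99          138.06             265.63
#>   viscous_modulus_kpa_s edr_pct
#> 1                 66.62   65.73
```

The generating E, η and h₀ come back within 0.05% (the residual discrepancy
is the one-frame quantization of contact detection and the finite-difference
strain rate). Peak stress ≈ 138 kPa is E times peak strain: at the strain
crest the rate is zero, so the viscous element contributes nothing there.

A synthetic two-group cohort (10 subjects × 2 legs per group), routed
through the comparison framework:

```r
spec <- cohort_spec(reference_cohort_spec(statuses = "time_zero"),
                    n_subjects = 10)
props <- cohort_properties(generate_cohort(spec, seed = 1))
compare_cohort(props)
#>      status              property      test statistic p.value stars
#> 1 time_zero  primary_thickness_mm student_t    -1.779 0.08318     .
#> 2 time_zero       peak_strain_pct student_t     3.302 0.00210    **
#> 3 time_zero       peak_stress_kpa student_t     0.221 0.82631
#> 4 time_zero    youngs_modulus_kpa student_t    -3.320 0.00200    **
#> 5 time_zero viscous_modulus_kpa_s   welch_t    -3.308 0.00248    **
#> 6 time_zero               edr_pct student_t    -1.204 0.23593
#>       diabetes      healthy
#> 1   12.59±2.46   14.07±2.79
#> 2   63.84±9.83  53.15±10.62
#> 3 146.21±44.41 143.10±44.55
#> 4 232.23±45.08 276.98±40.04
#> 5  32.28±18.25  60.36±33.28
#> 6  49.21±24.86  58.72±25.08
```

Each row reports the routed test (here the viscous modulus failed Bartlett's
homoscedasticity check, so it took the Welch route), the statistic, the
two-sided p-value, and per-group summaries formatted by their own normality
diagnostics. At this seed the thickness difference happens to miss α = 0.05
— single-cohort power for that contrast is around 80%, which the simulation
framework lets you quantify directly.

Group comparisons reported only as summary statistics can be checked with
the pooled t:

```r
t_from_summary(10, 64.4, 3.4, 10, 67.8, 4.9)
#>   statistic    df p.value
#> 1      1.80    18  0.0882
```

See `vignette("heelpad-methods")` for the model assumptions, the simulator's
design choices and validity domain, and the routing rules.

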