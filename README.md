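# bilayerDR

Monte Carlo simulation and analysis of spatially resolved diffuse
reflectance (DR) from layered turbid media, built around one question from
tissue optics: **where is the crossover point (Cp) of a bilayer sample —
the radial distance at which photons that traversed the bottom layer begin
to dominate the reflectance profile — and how does it depend on the
absorption of the two layers?**

For a homogeneous semi-infinite medium the DR profile decays as
`R(ρ) = (C₁/ρᵐ)·exp(−μ_eff·ρ)` with
`μ_eff = sqrt(3 μ_a (μ_s′ + μ_a))`, so `ln(R·ρᵐ)` is nearly linear with
slope `−μ_eff`. A bilayer whose top layer (thickness T) absorbs more than
its bottom layer shows two slopes, separated by the crossover point.
Random-walk and diffusion treatments predict

```
Cp ∝ T · (1 + sqrt(μ_a,2 / μ_a,1))
```

i.e. Cp is linear in `x = sqrt(μ_a,2/μ_a,1)`. The package simulates the
full tissue-phantom grid for that prediction (fixed `μ_s = 2.9 mm⁻¹`,
`g = 0.69`, `μ_s′ = 0.89 mm⁻¹`, `T = 2 mm`; top-layer
`μ_a ∈ {0.24, 0.41, 0.6} mm⁻¹`, bottom-layer
`μ_a ∈ {0.03, 0.09, 0.12} mm⁻¹`, detection 2–12 mm every 0.2 mm), extracts
the nine crossover points, and fits the linear relation.

It is intended for researchers in biomedical optics who want a
reproducible, self-contained implementation of the crossover-point method:
the transport kernel, the slope-based extraction criterion, the far-field
noise-limit analysis (secondary breaking point near `5/μ_eff` of the
bottom layer), and a synthetic noisy-measurement emulator for testing the
pipeline without laboratory data.

## What's inside

| Layer | Functions |
|---|---|
| Optics | `optical_properties()`, `reduced_scattering()`, `effective_attenuation()`, `noise_limit_distance()` |
| Transport | `simulate_dr()` (Rcpp kernel: Henyey–Greenstein scattering, Fresnel boundary, Russian roulette), `combine_profiles()`, `energy_audit()` |
| Profiles | `model_reflectance()`, `to_log_profile()`, `fit_global_slope()`, `local_slopes()` |
| Crossover | `cp_config()`, `extract_cp()`, `detect_secondary_breakpoint()` |
| Relation | `sqrt_ratio()`, `fit_cp_relation()`, `theory_consistency()` |
| Study | `build_grid()`, `run_study()`, `noise_model()`, `emulate_measurement()`, `write_study()` |
| I/O | `read_profile_csv()`, `write_profile_csv()` |

## Worked example

```r
library(bilayerDR)

top    <- optical_properties(mu_a = 0.6,  mu_s = 2.9, g = 0.69)
bottom <- optical_properties(mu_a = 0.03, mu_s = 2.9, g = 0.69)
grid   <- detection_grid(2, 12, 0.2)

mono <- simulate_dr(monolayer_medium(top), grid, sim_config(n_photons = 1e6, seed = 1))
bi   <- simulate_dr(bilayer_medium(top, bottom, thickness = 2), grid,
                    sim_config(n_photons = 1e6, seed = 2))
mono
#> <dr_profile> 50 bins over [2, 12) mm, 1e+06 photons, 0.4% of launched weight scored

fit <- fit_global_slope(to_log_profile(mono, m = 1), c(2, 5))
round(c(slope = -fit$slope, mu_eff = effective_attenuation(0.6, 0.89)), 3)
#>  slope mu_eff
#>  1.433  1.638

cp <- extract_cp(to_log_profile(bi), to_log_profile(mono), cp_config())
cp
#> <cp_result> Cp = 3.70 mm (slopes -1.168 -> -0.675, monolayer -1.433)
```

Reading the output: only ~0.4% of launched photons reach the 2–12 mm
detection annuli for this strongly absorbing monolayer. Its fitted
log-slope (1.43 mm⁻¹) sits below the closed-form `μ_eff` (1.64 mm⁻¹) —
at high absorption the diffusion-regime identification is approximate; see
the methods vignette (`vignettes/crossover-point-methods.Rmd`) for why and
for the opposite bias at low absorption. The bilayer profile tracks the
monolayer until 3.7 mm, where its local slope has moved more than
α = 20% of the monolayer slope away: past the crossover the slope relaxes
from −1.17 toward the bottom layer's much weaker attenuation (−0.68 over
the remaining scan).

The full nine-configuration study is one call (about 8 minutes at the
default 10⁷ photons per configuration):

```r
study <- run_study(build_grid(), sim_config(n_photons = 1e7),
                   cp_config(), monolayers = "top", master_seed = 1)
study$relation
#> <relation_fit> Cp = 6.675 * sqrt(mu_a2/mu_a1) + 1.893 mm  (R^2 = 0.9374, n = 8, 1 outlier(s) excluded)
```

All nine crossovers are found, ordered monotonically in the absorption
ratio, and linear in `sqrt(μ_a,2/μ_a,1)`. The slope/intercept split of the
fitted line depends strongly on the extraction threshold α and its noise
calibration — the methods vignette quantifies this (the same profiles
re-extracted with α between 0.1 and 0.3 move the slope across 2.4–8.8 mm)
and explains why a desk-scale photon budget shifts the split relative to
laboratory-scale studies.

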