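# cetransit

Cholesteryl ester transfer protein (CETP) shuttles cholesteryl esters
(CE) from HDL to LDL/VLDL through a ~60 Å hydrophobic tunnel that runs
the length of the molecule. Two quantitative questions sit at the heart
of that picture: *what does the tunnel look like* along the transfer
pathway (how wide, how hydrophobic, how does the cargo orient), and *how
fast* can a CE molecule traverse it under the driving force that the
lipoprotein particles themselves supply?

`cetransit` is an R package for analysts working on tunnel-mediated
lipid transfer. It provides:

- **Tunnel geometry**: probe-sphere diameter profiles along a transfer
  path, a greedy step-by-step pathway search, ligand-contact residues
  (strict < 2.4 Å center-to-center, the diameter of a hydrogen vdW
  surface), Shrake-Rupley solvent-accessible surface areas, and
  SASA-weighted Kyte-Doolittle hydrophobicity profiles in 1 Å arclength
  steps.
- **Transfer kinetics**: log-log least-squares fitting of the
  steered-transfer power law `Time (ns) = A × Force^−b` with broom-style
  `tidy()`/`glance()` methods, predictions with explicit extrapolation
  flags, and the published 18-force mean ± SD transfer-time table as a
  fixture.
- **Biophysics**: the Young-Laplace model `P = 2α/R` of lipoprotein
  internal pressure, the HDL−LDL pressure difference acting on the
  tunnel cross-section as a driving force in kcal/mol/Å, and conversion
  of radiolabel transfer rates (nmol/h/µg or µg/h/ml) into CE
  molecules/s per CETP and per-molecule transfer times.
- **Trajectory metrics**: Kabsch RMSD (proper rotations only), two-pass
  RMSF, radius of gyration, 0.25 Å grid molecular volumes, and radial
  distribution first peaks.
- **Synthetic data**: barrel structures with known inner-radius
  profiles, scheduled ligand trajectories, replicated force-time tables
  with log-normal scatter, overdamped 1-D Langevin first-passage times,
  and jittered monolayer lattices — so every analysis step is testable
  against construction oracles without running molecular dynamics.

The core model chain: the Laplace pressure difference between an HDL
(R ≈ 50 Å) and an LDL (R ≈ 110 Å) particle at monolayer surface tension
α ∈ [0.020, 0.033] N/m, acting on the circular ~6 Å tunnel
cross-section, gives a physiological driving force

    F = 2α (1/R_HDL − 1/R_LDL) · π(d/2)² ≈ 0.018–0.029 kcal/mol/Å,

which, inserted into the fitted power law `t = 475 · F^−2.75` ns,
predicts per-molecule transfer times of ~0.008–0.03 s (~33–125 CE
molecules/s per CETP).

## Worked example

```r
library(cetransit)

# Fit the power law to the shipped 18-force summary table
fit <- fit_power_law(ce_force_time_means(), weighting = "mean")
fit
#> Power-law fit: Time (ns) = 540.5 * Force^-2.799   (|r| = 0.9895, n = 18, forces 6-23)

# Physiological projection from the Young-Laplace driving force
physiological_prediction(list(A = 475, b = 2.75), c(0.020, 0.033))
#> # A tibble: 2 × 5
#>   surface_tension  force  time_s rate_per_s extrapolated
#>             <dbl>  <dbl>   <dbl>      <dbl> <lgl>
#> 1           0.02  0.0178 0.0310        32.3 NA
#> 2           0.033 0.0293 0.00781      128.  NA

# Radiolabel measurements, converted to per-molecule kinetics
round(rate_from_specific_activity(75.7), 2)  # 1.54 CE molecules/s/CETP
round(rate_from_plasma_flux(64), 2)          # 1.14 CE molecules/s/CETP

# Tunnel geometry on a synthetic barrel with a 2.0 Å constriction
b <- make_barrel(axis_length = 20,
                 inner_radius = function(s) ifelse(abs(s - 10) <= 3.5, 2.0, 3.3))
dp <- diameter_profile(b$structure, b$path)
dp[9:13, ]
#> # A tibble: 5 × 4
#>   arclength diameter open  outside
#>       <dbl>    <dbl> <lgl> <lgl>
#> 1         8     5.01 TRUE  FALSE
#> 2         9     4.27 TRUE  FALSE
#> 3        10     4.07 TRUE  FALSE
#> 4        11     4.27 TRUE  FALSE
#> 5        12     5.01 TRUE  FALSE
autoplot(dp)
```

The fit on the per-force means gives an exponent of 2.80 with |r| =
0.989 — close to, but not identical with, the 2.75/0.96 obtained from
all 72 replicate pulls, of which only the means are published. The
mid-constriction diameter (4.07 Å at arclength 10) sits slightly above
the nominal 4.0 Å because the probe center may move within its search
ball toward the constriction shoulders.

The surrogate ligand trajectory, hydrophobicity profiling, pathway
search and Langevin first-passage generators are demonstrated in the
methods vignette (`vignettes/cetransit-methods.Rmd`).

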