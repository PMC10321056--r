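# umbrellabind

Umbrella-sampling free-energy analysis for host–guest binding along a
cavity axis: binned WHAM estimation of the potential of mean force (PMF),
standard-state binding free energies under a flat-bottom cylinder
restraint, hydration-shell and cavity-wetting statistics, and fixed-charge
pair-energy profiles — plus a seeded Brownian-dynamics generator of
synthetic umbrella datasets with analytically known ground truth, so every
estimator can be validated end-to-end.

The package is aimed at people analysing ion binding to macrocyclic hosts
(or any quasi-1-D binding coordinate) who want the complete
window-series → PMF → ΔG° chain as tested, reusable functions rather than
ad-hoc scripts.

## The method in brief

Umbrella windows harmonically restrain the signed distance `z` between
the guest ion and the cavity centre (centre of geometry of the ring
atoms), while a flat-bottom cylinder of radius `R_cyl` confines lateral
motion.  Window histograms are combined by the WHAM self-consistency
equations

    p_b ∝ Σ_i H_ib / Σ_i N_i exp[(f_i − b_ib)/RT]
    exp(−f_i/RT) = Σ_b exp(−b_ib/RT) p_b

into an unbiased distribution, and `W(z) = −RT ln p(z)` is referenced to
zero over a declared bulk region.  Each window's post-equilibration data
are split into three equal-duration blocks; the minimum of the block-mean
profile is the binding free energy and the SD of the per-block minima its
error.  The cylinder restraint is converted to standard state
(C⁰ = 1/1661 Å⁻³) by

    ΔG_corr = −RT ln(π R_cyl² / A⁰),   A⁰ = π r₀² ≈ 170 Å²,

where `r₀` is the radius of a sphere of standard volume; the correction
vanishes when the cylinder cross-section equals the standard surface.  An
integral estimator, `ΔG = −RT ln(C⁰ K_b)` with
`K_b = π R_cyl² ∫ exp(−W/RT) dz`, is provided as a cross-check.

Units throughout: kcal mol⁻¹, Å, ps, K.

## Worked example

Simulate a 16-window dataset on the default synthetic landscape (central
well −6 kcal/mol at z = 0, flanking −4 components at ±3.5 Å, bulk beyond
12 Å), estimate the PMF with three blocks, and convert to a
standard-state binding energy:

```r
library(umbrellabind)

model   <- default_landscape()
layout  <- umbrella_layout(0, 15, 1, k_z = 1.195, r_cyl = 2.5, k_fb = 11.95)
windows <- generate_umbrella_dataset(
  model, layout, brownian_params(n_steps = 5e4, seed = 1))

pmf <- block_pmfs(windows, n_blocks = 3, equil_discard = 50,
                  reference_region = c(13, 15))
pmf$mean
#> PMF profile: 209 bins (195 occupied), z in [-2.65, 18.15] A
#>   min W = -6.856 kcal/mol at z = 0.15 A; reference region [13.00, 15.00]

dg_from_minimum(pmf$mean, pmf$blocks, r_cyl = 2.5)
#> Binding free energy (minimum method):
#>   dG_min   =   -6.856 kcal/mol at z = 0.15 A
#>   dG_corr  =    1.277 kcal/mol
#>   dG_total =   -5.579 +/- 0.251 kcal/mol

min(histogram_overlap(windows)$overlap)
#> [1] 0.352
```

Reading the output: the PMF minimum sits in the central well
(z ≈ 0), 6.86 kcal/mol below bulk; the +1.28 kcal/mol term is the
standard-state correction for the 2.5 Å cylinder; the ±0.25 is the
scatter of the three block minima.  Adjacent-window histogram overlaps of
~0.35 are comfortably above the 0.03 warning threshold.  Because the
landscape is synthetic, the result can be checked against the exact
profile:

```r
truth <- analytic_pmf(model, 2.5, pmf$mean$z, reference_region = c(13, 15))
occ <- pmf$mean$occupied
sqrt(mean((pmf$mean$W[occ] - truth$W[occ])^2))
#> [1] 0.107   # kcal/mol RMSE vs ground truth
```

`run_pipeline()` wires the same stages (plus solvent-frame generation,
hydration profiles and wetting statistics) behind one YAML-configurable,
fully seeded entry point; `inst/cli/umbrellabind.R` exposes the stages as
shell subcommands.  See the methods vignette
(`vignettes/umbrella-binding-methods.Rmd`) for the model, assumptions and
numerical choices.

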