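---
title: "Umbrella sampling, WHAM and standard-state binding energies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Umbrella sampling, WHAM and standard-state binding energies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umbrellabind)
```

## The problem

A macrocyclic host such as biotin[6]uril binds halide anions in a narrow,
slightly hydrophobic cavity.  The binding free energy can be computed from
molecular simulation by *umbrella sampling*: the ion is dragged along a
reaction coordinate — the signed z distance between the ion and the centre
of geometry of the ring of inward-pointing cavity carbons — with a ladder
of harmonic restraints, and the biased window histograms are recombined
into a potential of mean force (PMF) `W(z)`.  Because binding and
unbinding events in the lateral (xy) directions are rare on window time
scales, the ion is additionally confined by a flat-bottom cylinder of
radius `R_cyl` about the cavity axis: lateral motion is free inside the
cylinder and harmonically walled outside.  That confinement is what makes
a one-dimensional PMF convertible to a standard-state binding free energy
by a closed-form area correction.

This package implements the complete analysis chain — reaction-coordinate
geometry, restraint energies, binned WHAM with histogram-overlap
diagnostics and block-averaged errors, the standard-state conversion,
hydration-shell and cavity-wetting statistics, and fixed-charge pair
energies — together with a Brownian-dynamics generator of synthetic
umbrella datasets whose ground truth is known analytically.  The
generator exists so that every estimator in the package can be validated
end-to-end against exact answers; it is not a molecular-dynamics engine.

Internal units everywhere: kcal mol⁻¹, Å, ps, K, with
R = 1.98720425×10⁻³ kcal mol⁻¹ K⁻¹ and a default temperature of
298.15 K.  `convert_force_constant()` translates GROMACS-style
kJ mol⁻¹ nm⁻² force constants (exact factor 418.4).

## The synthetic model system

`model_potential()` defines a separable surface

$$U(x,y,z) = U_z(z) + \tfrac12\,k_r\,(x^2+y^2),
\qquad U_z(z) = \sum_i A_i e^{-(z-c_i)^2/2w_i^2},$$

a sum of Gaussian wells/barriers on the axial coordinate plus harmonic
lateral confinement.  Separability makes the cylinder-restrained PMF
analytic: the radial Boltzmann integral is a z-independent constant, so
`analytic_pmf()` returns `U_z` plus a constant fixed by the bulk
reference region (the closed form for the radial integral is
`(2πRT/k_r)(1 − e^{−k_r R_{cyl}^2/2RT})`).

`default_landscape()` is the reference system used by the tests and the
acceptance script: a central Gaussian of amplitude −6 kcal/mol at z = 0,
flanking −4 kcal/mol components at z = ±3.5 Å, and a bulk plateau
(|U_z| < 10⁻⁴ kcal/mol) beyond 12 Å — the qualitative shape of an anion
PMF through a cavity with a central binding site and secondary portal
sites.  The Gaussian widths (1.6 Å) were fixed once by a smoothness
criterion: the most negative curvature of `U_z` (≈ −1.05 kcal mol⁻¹ Å⁻²)
stays above −k_z for the standard umbrella strength
k_z = 1.195 kcal mol⁻¹ Å⁻² (= 500 kJ mol⁻¹ nm⁻²), so every biased window
samples a unimodal distribution and no window straddles a first-order
jump.  A consequence worth knowing: at these widths the flanking
components merge with the central well into a pronounced shoulder rather
than separate local minima.

## The Brownian-dynamics sampler

`simulate_window()` integrates overdamped Langevin (Euler–Maruyama)
dynamics,

$$\Delta r = -\frac{D}{RT}\nabla(U+U_\text{bias})\,\Delta t
  + \sqrt{2D\Delta t}\,\xi,$$

with no inertia or hydrodynamics: only the stationary distribution
matters for PMF estimation, and this is the simplest scheme whose
stationary law converges to Boltzmann as Δt → 0.  There are no periodic
boundaries; the radial harmonic term plus the flat-bottom wall confine
the particle.

Two numerical guards apply:

* **Stability bound.** The deterministic drift `D|∇U|Δt/RT` of every
  step is checked against a declared bound (default 0.5 Å); exceeding it
  aborts the window with a diagnostic.  The bound deliberately excludes
  the noise term — a bound on the full displacement would trip on
  ordinary ~3.5σ Gaussian tails at a rate of ~5×10⁻⁴ per step.
* **Discretisation budget.** Euler–Maruyama inflates stationary variances
  by ≈ κDΔt/2RT for local curvature κ.  Defaults D = 1.5 Å² ps⁻¹,
  Δt = 0.01 ps keep this below ~4% at the landscape's stiffest point
  (κ ≈ 3 kcal mol⁻¹ Å⁻²) while keeping the worst-case wall drift
  (≈ 0.38 Å at the cylinder wall, k_fb = 5000 kJ mol⁻¹ nm⁻² and typical
  overshoots) under the stability bound.  At fixed step count, statistical
  precision and discretisation bias both grow with the product D·Δt, so
  these defaults sit deliberately near the bound.

Seeding: each window's RNG seed is `master_seed + window_index`, so a
dataset is bit-for-bit reproducible from one integer, and the provenance
(model, seeds, restraints) is attached to the dataset and written to the
manifest.

The diffusion constant is not meant to be a physical ion diffusivity;
windows are a few nanoseconds of model time with relaxation times around
0.5 ps, chosen so that a full 26-window dataset is sampled in seconds.
What the generator does **not** emulate: explicit solvent forces,
electrostatics, polarisation, host flexibility, or realistic
autocorrelation structure.  Passing recovery tests therefore demonstrates
the correctness of the estimators, not the adequacy of any force field or
sampling protocol on real systems.

## WHAM

`wham()` implements the standard binned self-consistency iteration

$$p_b \propto \frac{\sum_i H_{ib}}{\sum_i N_i\,e^{(f_i - b_{ib})/RT}},
\qquad e^{-f_i/RT} = \sum_b e^{-b_{ib}/RT}\,p_b,$$

iterated until the largest change in any window free energy `f_i` falls
below `tol`.  Binned WHAM (rather than binless MBAR) is the reference
implementation because the analysis it models is histogram-based; MBAR
would be a drop-in alternative for the same module surface.

Numerical and design choices:

* Defaults: bin width 0.1 Å, tol 10⁻⁷ kcal mol⁻¹, max 10⁵ iterations.
  Convergence failure is an error (with the final residual), not a
  warning.
* Only the z-umbrella enters the bias matrix.  The xy flat-bottom
  cylinder is identical in all windows, i.e. part of the restrained
  system itself; that is exactly the premise under which the area
  correction below converts the PMF minimum to standard state.
* Empty bins are masked `NA`, never interpolated; TSV exports keep the
  gaps explicit.
* Windows that share no occupied bin form disconnected clusters whose
  relative free energies are undetermined; `wham()` refuses to run and
  names the clusters.  `histogram_overlap()` reports the adjacent-pair
  overlap coefficient `Σ_b min(p₁, p₂)` and flags pairs below 0.03.
* No automatic symmetrisation about z = 0; signed coordinates are kept
  throughout.

`block_pmfs()` reproduces the standard uncertainty protocol: discard an
equilibration span from each window, cut the remainder into (by default)
three contiguous equal-duration blocks *by simulation time*, run WHAM per
block, and report per-bin mean and standard deviation across blocks.  The
pipeline default discards the first 10% (200 ps of a 2000 ps window),
mirroring the 1-ns-of-25 convention of nanosecond-scale studies.

**Bulk reference.** `W` is referenced to zero over a declared bulk
region.  The generic fallback is the outermost 2 Å of the sampled range,
but the outermost bins of a dataset hold few, highly correlated samples,
and their noise shifts the whole profile.  The pipeline therefore
defaults to an explicit, solidly sampled bulk window of 20–25 Å (the
plateau begins at 12 Å; windows extend to 25 Å).

## Standard-state binding free energy

With the ion confined to a cylinder of radius `R_cyl`, the binding
constant of a bulk-referenced profile is

$$K_b = \pi R_\text{cyl}^2 \int_\text{site} e^{-W(z)/RT}\,dz,
\qquad \Delta G = -RT\ln(C^0 K_b),$$

with `C⁰ = 1/1661 Å⁻³`.  The package's headline estimator is instead the
*minimum-plus-correction* form used when tabulating host–guest energies:
the minimum of the three-block mean profile is the uncorrected binding
energy, the SD of the per-block minima its error, and

$$\Delta G_\text{corr} = -RT \ln(\pi R_\text{cyl}^2 / A^0)$$

converts to standard state, where `A⁰ = π r₀²` is the surface of the
circle whose radius is that of a sphere of standard volume 1661 Å³.
`standard_area(1661)` evaluates to 169.57 Å² (170 to two significant
figures); the package uses the exact value so that the correction
vanishes identically at `R_cyl = √(A⁰/π)`.  At 298.15 K the correction is
+1.28 kcal/mol for `R_cyl` = 2.5 Å and +0.88 kcal/mol for 3.5 Å.  The
correction is treated as exact in the error budget; only block scatter
enters `dG_sd`.  Positive (unfavourable) totals are reported as-is.

`dg_from_integral()` implements the K_b route (trapezoid on the bin grid)
as an independent cross-check; for a deep, narrow well the two estimators
agree to within an RT-scale width factor.  Ties in the minimum are broken
toward smaller |z|.

## Hydration shells and cavity wetting

The solvent analyses operate on per-frame coordinates (ion, pseudo-water
oxygens, host):

* `count_shell()` counts waters within a cutoff of the ion and host atoms
  within a second cutoff.  Both counts use a **closed** interval
  (≤ cutoff), a convention fixed to make tests bit-exact.  Defaults are
  3.4 Å (water oxygens, a typical first-shell distance) and 4.0 Å (host
  contacts); both are explicit parameters because real-world choices
  vary, and every output records the cutoffs used.
* `hydration_profile()` bins frames by the reaction coordinate (signed by
  default, foldable to |z|) and reports per-bin means and SDs of both
  counts; empty bins carry `n_frames = 0`.
* `classify_wetting()` marks a frame wetted when any water lies within
  3 Å (configurable) of the cavity centre, the standard occupancy
  criterion for a small cavity, and derives the de-wetted fraction,
  transition count and per-state dwell times.  Dwell times at the trace
  edges are censored intervals: they are excluded from dwell-time means
  but included in the occupancy fractions.

The pseudo-solvent generator drives these analyses with a known
statistical model: shell-water counts are Poisson with mean
`bulk_count_mean · s(d)`, where `s(d) = 1/(1+e^{-(d-r_cav)/h})` is a
logistic replacement curve (hydration lost as the ion enters the cavity),
and cavity occupancy follows a two-state Markov chain with rates `k_wet`,
`k_dry` sampled at the frame interval (stationary wetted fraction
`k_wet/(k_wet+k_dry)`; the chain is initialised from its stationary
law).  One caveat by construction: shell waters are placed around the
*ion*, so when the ion sits inside the cavity those waters can also
trigger the wetting criterion; wetting-statistics tests therefore park
the ion in bulk.

## Pair energies

`lj_12_6()` (Lorentz–Berthelot combination) and `buffered_14_7()`
(Halgren form with the standard buffering constants δ = 0.07, γ = 0.12
and AMOEBA combination rules: cubic-mean `r_min`, HHG ε) both evaluate to
exactly −ε at `r_min`.  The buffered form is softer-cored: on the
repulsive wall it lies *below* the 12-6 curve of the same `(r_min, ε)`.
`fit_lj_to_14_7()` fits 12-6 parameters to a 14-7 curve by
Levenberg–Marquardt least squares on a distance grid (range and weights
are explicit parameters, since published fits rarely state them).
`coulomb()` uses the vacuum constant 332.0637 kcal Å mol⁻¹ e⁻².
`interaction_profile()` sums guest–host pair energies per frame, bins by
the reaction coordinate, and shifts the vdW and Coulomb components so
each is zero in the bin containing the 15 Å reference distance; the
components sum to the total exactly.  Multipoles and polarisation are
deliberately out of scope: the module shows what a fixed-charge
description yields.

## Problem sizes and determinism

The validation suite and the acceptance script use: 26 windows (0–25 Å,
1 Å spacing, k_z = 1.195 kcal mol⁻¹ Å⁻², R_cyl = 2.5 Å,
wall 5000 kJ mol⁻¹ nm⁻²) × 2×10⁵ steps for PMF/binding recovery;
10⁶-step trajectories for the free-diffusion, equipartition and Boltzmann
histogram checks (the latter thinned 500× so a G-test's chi-square null
applies); 10⁵ frames for the Markov wetting statistics; and 6×10³ frames
for hydration-curve recovery.  Smaller replicas of the same structure
back the unit tests.  Every random quantity descends from one master
seed, and rerunning any pipeline with the same configuration reproduces
outputs byte-for-byte.

## Known limitations

* The generator's dynamics are caricatures: realistic water exchange,
  host flexibility and ion autocorrelation are absent, so error bars
  measured here say nothing about how many nanoseconds a real system
  needs.
* No autocorrelation-based effective-sample-size correction; uncertainty
  comes from the three-block protocol only.
* One-dimensional PMFs only; no 2-D umbrella grids.
* The integral estimator depends on user-declared site bounds; it is a
  cross-check, not the headline number.
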