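---
title: "Ensemble modelling of flexible antibodies against solution scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble modelling of flexible antibodies against solution scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexsas)
```

## The problem

An IgG antibody is three compact subunits — two antigen-binding Fabs and one
glycosylated Fc — joined by short, genuinely flexible hinge peptides. A 1-D
small-angle X-ray or neutron scattering (SAXS/SANS) curve of such a molecule
in solution is an orientational and conformational average: no single rigid
structure explains it, and crystal structures capture only one hinge
geometry. The established way to interpret these curves is ensemble
modelling: generate a large library of stereochemically acceptable
conformers by varying only the hinge torsions, compute each conformer's
theoretical curve, rank the conformers against the measured curve, and
characterise the best-fitting subset. `flexsas` implements that workflow
end to end, together with the model-free analytics (Guinier,
cross-sectional Guinier, P(r), normalized Kratky) and a hydrodynamic
cross-check (sedimentation coefficients from convex hulls), so X-ray,
neutron and analytical-ultracentrifugation views of the same molecule can
be compared within one package. A typical application is asking whether
removing the two conserved Asn-297 N-glycans (about 5 kDa of a ~148 kDa
molecule) changes the conformational ensemble.

## Conformer generation: torsion-angle Monte Carlo

`tamc_sample()` runs a Markov chain over hinge conformations. Each move
picks one variable backbone dihedral — phi (the N–CA bond) or psi (CA–C) of
a residue declared flexible — uniformly at random, draws a rotation from
the discrete grid of multiples of the `step` (default 15 degrees, a grid
fine enough to reach all relevant hinge geometries while keeping the state
space countable) over (−180, 180] excluding zero, applies it rigidly to
every atom downstream of the bond, and accepts the move if and only if no
steric clash results. Accepted frames become the new current state;
rejected moves revert fully. Everything outside the declared hinge
residues moves only as a rigid body, so Fab and Fc internal geometry is
bit-preserved (the test suite asserts internal RMSD < 1e-6 nm).

The clash criterion is a heavy-atom centre-to-centre cutoff, default
0.20 nm, between atoms of different rigid bodies or involving the linker,
with directly bonded (1-2) and angle-connected (1-3) pairs excluded. A
distance cutoff without van-der-Waals radii is deliberately conservative
and has one tunable number; it is exposed as `cutoff`. Clash evaluation
uses a spatial cell grid (compiled code), so its cost is near-linear in
atom count.

Two choices here were genuinely open:

* **Chain vs restart semantics.** Moves chain from the last accepted state
  (a random walk over conformation space) rather than restarting from the
  input structure each time. Chaining is standard Monte Carlo usage and
  explores the space far more widely; `tamc_sample()` documents it and a
  restart variant can be emulated with `n_moves = 1` batches.
* **Angle proposal.** Uniform over the full step grid rather than ±1 step;
  with a free dihedral this makes the marginal distribution uniform over
  the 24 grid angles almost immediately, which the suite verifies with a
  3-sigma multinomial check over >10,000 accepted moves.

## Theoretical curves

Two independent evaluators compute `I(Q)` from an atomic model in vacuo:

* `debye_intensity()` — the Debye double sum evaluated through a weighted
  pair-distance histogram (default bin 0.01 nm). This is the exact
  orientational average and the package default.
* `golden_grid_intensity()` — the average of `|sum b_i exp(iQ u.r_i)|^2`
  over quasi-uniform directions from a golden-ratio (Fibonacci) spiral
  (default 300 directions), the construction used by grid-based SAS
  calculators.

They agree within 0.5% relative over Q ≤ 1.5 nm⁻¹ on every test model and
serve as mutual oracles. X-ray per-atom amplitudes are atomic numbers
(electron counts): Q-independent, no excluded-volume term, and no hydration
shell for either contrast. These are stated approximations, adequate for
the low-Q regime (Q ≤ 1.5 nm⁻¹) where a hydration monolayer mainly affects
larger Q; a hydration hook is deliberately absent rather than half-built.
Neutron amplitudes are tabulated bound coherent lengths, with labile
(N/O/S-bonded) hydrogens mixed toward deuterium as
`b = (1 − f_ex·f_D2O)·b_H + f_ex·f_D2O·b_D`; crystal structures without
explicit hydrogens get per-residue implicit-H scattering folded uniformly
into each residue's heavy atoms from a built-in count table.

## Model-free analytics

* **Guinier** (`guinier_fit()`): least squares of ln I vs Q²,
  `R_G = sqrt(−3·slope)`. Default X-ray window 0.10–0.22 nm⁻¹ and neutron
  window 0.07–0.27 nm⁻¹ (presets in `q_windows`, including the wider
  0.10–0.27 X-ray variant); the antibody validity bound Q·R_G ≤ 1.5 is
  reported as a flag, never silently enforced. Note that the unweighted
  log-linear fit carries a shape-dependent truncation bias that reaches
  about 1% for a homogeneous sphere when the window tops at Q·R_G = 1.0;
  analytic validation in the tests therefore fits lower windows
  (top at Q·R_G ≈ 0.6–0.9), which sit inside the validity bound.
* **Cross-sectional Guinier** (`cross_section_fit()`): ln(I·Q) vs Q²,
  `R_XS = sqrt(−2·slope)`; windows 0.29–0.52 (R_XS-1, Fab–Fc separation)
  and 0.66–1.05 nm⁻¹ (R_XS-2, subunit cross-section).
* **P(r)** (`ift_pr()`): indirect transformation by second-difference
  (Tikhonov) regularised non-negative least squares with P(0)=P(dmax)=0,
  solved by NNLS; the regularisation weight defaults to an L-curve corner
  over a 12-point log grid and is overridable. `estimate_dmax()` scans a
  0.5 nm grid and takes the smallest dmax whose residual is within 5% of
  the scan minimum — the operational version of reading where P(r) meets
  zero. `find_pr_peaks()` returns the modal distances M1 (global maximum)
  and M2 (next local maximum of a smoothing-spline fit, or a shoulder
  detected as a significant concave excursion of the spline's second
  derivative; amplitude thresholds of 2% of the peak height/curvature
  reject smoothing wiggles; ties break toward smaller r).
* **Normalized Kratky** (`kratky_normalized()`): (Q·R_G)²·I/I(0) vs Q·R_G.
  A globular body peaks at x = √3 with height 3/e; peak positions beyond
  that diagnose flexibility and disorder.

## Ensemble scoring, selection and PCA

`score_ensemble()` puts every frame's Debye curve on the experimental grid
(use `regularize_curve()` first: uniform Q spacing, extrapolated to Q = 0
with the Guinier model below the first measured point; 680 points for
X-ray and 72 for neutron on 0–1.5 nm⁻¹ are the standard grids) and
computes the R-factor

R = 100 · Σ|I_expt − η·I_model| / Σ|I_expt|,

with η fixed by matching the experimental forward scattering I(0) — the
reference convention; a least-squares η exists behind an explicit flag.
χ² is intentionally not offered as a ranking metric: the target use case
is curves without usable per-point errors, and the R-factor is the sole
criterion. `select_best()` keeps the n = 100 smallest R-factors (ties to
the smaller model id), and `chevron_table()` bins best R-factor against
model R_G — a well-formed analysis shows a chevron-shaped minimum at the
true R_G, within the ±2% band used for comparison.

`pca_cluster()` takes best-fit frames (align them first with
`superpose_set()`, typically on the Fab atoms), optionally strips glycan
atoms so glycosylated and deglycosylated sets are compared on identical
protein atoms, and eigen-decomposes the coordinate covariance over frames
(coordinates only, no mass weighting). Grouping uses k-means on the top-3
projections with a fixed seed and 50 restarts; the number of groups is a
convention (default 4), not an optimum, so the mean silhouette width is
reported for the user to judge. Each group's centroid model is the member
frame closest to the group mean in PC space. `fc_occupancy_summary()`
reduces "how much space does the Fc explore" to one number: the per-atom
positional standard deviation over frames averaged over the Fc selection.

## Hydrodynamics

`s20w_correct()` standardises an observed sedimentation coefficient to
water at 20 °C through the buffer viscosity/density and the partial
specific volume (reference constants η = 0.0100194 poise,
ρ = 0.99823 g/ml are fixed named constants so the correction is
bit-reproducible). `svedberg_mass_scaled_s()` applies the constant-
frictional-ratio scaling s ∝ M^(2/3) — e.g. a 5.0 kDa deglycosylation loss
on a 148.1 kDa, 6.52 S antibody predicts a 0.15 S reduction.
`hull_s20w()` reduces hull-based hydrodynamics to its sedimentation core:
convex hull volume of all atoms (glycans included) → equivalent-sphere
radius → Stokes radius after adding a hydration thickness (default
0.28 nm) → the Svedberg equation. The 3-D hull is an incremental
(beneath-beyond) algorithm validated against closed forms. Agreement with
AUC-style observations within ±0.21 S is the conventional consistency
band. Full hydrodynamic shell modelling (frictional ratios, diffusion
coefficients) is out of scope.

## The synthetic-data generator

`make_mock_antibody()` builds the package's study object: two Fab and one
Fc ellipsoidal lobes of uniform pseudo-atoms (default 150 per lobe, unit
scattering length) in a Y arrangement, joined by two flexible tripeptide
linkers whose residues carry N/CA/C pseudo-backbone atoms on a zig-zag
path, with phi/psi declared variable exactly as for a real hinge. Default
dimensions are set to the antibody scale — R_G ≈ 4.9 nm (lobe spacing is
scaled once, deterministically, to the `target_rg`), maximum dimension
13–17 nm, nominal mass 148.1 kDa — so synthetic experiments probe the same
Q regime as real antibody data. `make_sphere_model()` /
`analytic_sphere_curve()` / `analytic_sphere_pr()` provide the closed-form
sphere oracles, and `simulate_experiment()` adds mean-zero Gaussian noise
with σ(Q) = σ₀·I(Q)·(1 + g·Q), a simple stand-in for counting statistics.
All generators are seed-deterministic.

What the mock does **not** emulate: real residue chemistry and sidechains,
instrument resolution smearing, incoherent backgrounds, concentration-
dependent structure factors, and the hydration shell. Passing tests on the
mock therefore demonstrate the correctness of the sampling/scoring/
selection machinery, not the accuracy of any particular atomic force
field or solvent model on real data.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale versions of the
full analysis: 10,000 Monte Carlo moves (the full-scale runs this workflow
is built for use move budgets of order 10⁵–10⁶; budgets are configuration
values, not constants), best-100 selection over the ~7,500 accepted
frames, 680-point X-ray grids, 20,000-point sphere clouds for hull
validation. Histogram bin width defaults to 0.01 nm (0.02 nm in bulk
scoring, where the binning error is far below the noise); golden-grid
direction counts default to 300. Degenerate inputs are rejected loudly:
positive Guinier slopes, single-atom P(r), identical-frame PCA, coplanar
hulls, neutral buoyancy.

## A worked run

```{r example, eval = FALSE}
model <- assign_scattering_lengths(make_mock_antibody())
expt <- simulate_experiment(model, noise = noise_spec(0.01, seed = 11),
                            n_q = 680, q_max = 1.5)
cfg <- pipeline_config(model = model,
                       curves = list(list(curve = expt, concentration = 1)),
                       n_moves = 10000, seed = 1, dmax = 16)
report <- run_pipeline(cfg)
report
```

The report carries, per curve: the Guinier/cross-section fits, P(r) with
D_max/M1/M2, Kratky peaks, all R-factors with the best-100 ids and the
chevron table; and globally: PCA groups with centroids, the Fc spread
statistic, hull s20,w values, and a provenance block (seeds, config hash,
package version) sufficient to reproduce the run exactly.

## Known limitations

* X-ray amplitudes ignore Q-dependent atomic form factors and excluded
  volume; do not push the curves past Q ≈ 1.5 nm⁻¹.
* The clash test is a single distance cutoff; it will accept marginally
  tighter packing than a van-der-Waals model would.
* The IFT is a generic regularised NNLS, not a reimplementation of any
  specific indirect-transform program; its automatic regularisation is an
  L-curve corner, which can under-smooth very noisy curves (set `alpha`
  explicitly there).
* Torsion sampling covers backbone phi/psi of declared residues only — no
  sidechain or glycan torsions.
* The deposited best-fit coordinate sets of the reference antibody study
  are not redistributed with the package; validation against them runs
  only when the user places those files under
  `inst/extdata/reference_models/` (`glycosylated_bestfit.pdb`,
  `deglycosylated_bestfit.pdb`) before installation, and the corresponding
  acceptance test fails (rather than silently skipping) in their absence.
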