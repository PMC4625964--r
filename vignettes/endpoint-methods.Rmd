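---
title: "End-point binding free energies and trajectory analysis: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{End-point binding free energies and trajectory analysis: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdbind)
```

mdbind post-processes protein–ligand MD trajectories into end-point binding
free energy estimates and the structural-dynamics observables that support
them. This vignette records the models, the conventions chosen where the
methods literature leaves latitude, and the limits of what the synthetic
validation can show.

## Unit system and data model

Lengths are Angstrom, times ps, energies kcal/mol, charges elementary
units, masses amu — everywhere; conversion happens only at file
boundaries. A `trajectory` stores frames as an `nframes × 3N` matrix (the
bio3d layout), a `topology` carries the static per-atom force-field
parameters (charge, LJ sigma/epsilon, intrinsic Born radius and descreening
scale, mass, donor/acceptor flags), the receptor/ligand selections, and an
optional harmonic bond list. Because PDB has no fields for any of this, the
parameters travel in a versioned YAML sidecar (`read_topology_sidecar()`
documents the schema). Atom indices are 1-based throughout, as is idiomatic
in R; PDB serials appear only in files.

## Frame selection

Frames are picked on a closed time grid `start + k·stride`, matched to
trajectory timestamps within half the native frame spacing. The customary
snapshot protocol "n snapshots at an interval of s over the last W ns" is
expressed by `last_window_selection()`, which starts the grid at
`end − W + s`: snapshots mark the *ends* of stride intervals, so a 20-ns
window at 100 ps yields exactly 200 frames and at 400 ps exactly 50. (The
alternative closed-window reading `[end − W, end]` would give 201 and 51;
the end-anchored convention reproduces the counts used in practice.)

## Molecular-mechanics interaction terms

`coulomb_energy()` and `lj_energy()` sum all receptor–ligand pairs with no
cutoff: a non-bonded cutoff belongs to the MD engine that generated the
frames, not to end-point rescoring of an isolated complex (a `cutoff`
argument exists but defaults off). The Coulomb constant is fixed at the
AMBER value 332.0637 kcal·mol⁻¹·Å·e⁻². LJ parameters are stored as
(sigma, epsilon) and combined by Lorentz–Berthelot rules; A/B-coefficient
inputs must be converted at import. 1-2/1-3/1-4 exclusions never arise
because the two selections are disjoint molecules. Component tables quote
the per-snapshot dispersion `sqrt(Σ(x_i − x̄)²/(N−1))` — the sample
standard deviation over snapshots, which is how "standard errors" are
conventionally printed in end-point component tables; it is *not* the
standard error of the mean, and it is not invariant under frame
duplication.

## Generalized Born polar solvation

Effective Born radii follow the pairwise HCT descreening integral with the
OBC tanh correction: with reduced radius `ρ̃_i = ρ_i − offset` (offset
0.09 Å), integral `I_i` and `ψ = I_i ρ̃_i`,

    1/R_i = 1/ρ̃_i − tanh(αψ − βψ² + γψ³)/ρ_i.

The default shape constants are `(α, β, γ) = (0.8, 0, 2.909125)` — OBC
model I (the Amber `igb = 2` set); model II `(1.0, 0.8, 4.85)` is
selectable via `gb_params(variant = "II")`. An isolated atom has
`R_i = ρ_i − offset` exactly. The polar energy is the standard GB
cross-term sum with `f_GB = sqrt(r² + R_iR_j exp(−r²/4R_iR_j))`, prefactor
`−k_e(1/ε_in − 1/ε_out)/2`, self-terms included, which reduces to the Born
ion formula for a single charge. Binding changes recompute the radii for
each state (complex, receptor, ligand) from the same frame, so the
separated states lose the partner's descreening.

The SIE reaction-field term ΔG^R is produced by this same GB machinery at
the interior dielectric D_in = 2.25. This is a deliberate surrogate for
the boundary-element Poisson solver used in the original SIE
parameterization: the package documents it as such, and the packaged
component tables let the affine combination be checked independently of
the solvent model.

## Surface areas

`sasa()` is Shrake–Rupley with golden-spiral point sets — fully
deterministic, no RNG, so areas are bit-reproducible. A single sphere at
960 points is accurate to well under 1%. The SIE "molecular surface" term
is approximated by the accessible surface with all radii scaled by
ρ = 1.1 and a zero probe (`surface_params(0, n, 1.1)`); the MM-GBSA
non-polar term uses unscaled radii with a 1.4 Å probe. A true Connolly
surface engine is out of scope. Note one numerical consequence of sampled
surfaces: areas are exactly invariant under translation (points ride on
atom centers) but invariant under rotation only to quadrature resolution
(< 1% at 960 points); the GB quantities, being functions of interatomic
distances, are rigid-motion invariant to machine precision.

## Superposition, RMSF, DCCM, PCA — and when to fit

`kabsch_superpose()` is the SVD solution with the reflection excluded;
fitting is mass-unweighted (the Cα-only analyses make mass weighting a
constant). RMSD uses the backbone (N, CA, C, O) by convention; RMSF, the
cross-correlation matrix and covariance PCA use Cα. The fitting reference
for the fluctuation analyses is obtained by one fit-to-mean iteration: fit
all frames to frame 1, form the mean structure, refit to it. Zero-variance
atoms get zero off-diagonal correlation (with a warning) rather than NaN.

The fluctuation operations take a `fit` argument, default `TRUE`. The
default is right for raw MD frames, which carry arbitrary global rigid
motion. It is *wrong* for synthetic frames generated as displacements
about a fixed reference: a Kabsch fit absorbs precisely the common-mode
part of the displacement field, so a designed uniform positive correlation
(which *is* mostly common-mode motion) cannot survive it — after removing
the mean over N atoms, a design correlation c among all atoms collapses to
roughly (c − c̄)/(1 − c̄) ≈ 0. The parameter-recovery suite therefore runs
with `fit = FALSE`, which is the statistically faithful setting for frames
already expressed in a common frame; the rigid-motion-invariance property
tests run with the default fit. This is also why a two-atom
anti-correlation check is only expressible unfitted: two atoms cannot
define a superposition.

## End-point assembly

`mmgbsa_combine()` is the exact five-term sum; the entropy field stores the
signed quantity −TΔS (positive = binding penalty) and is simply added.
Missing entropy yields a flagged enthalpy-only estimate. `sie_score()` is
`α(E_c + ΔG^R + E_vdW + γ·ΔMSA) + C` with defaults α = 0.1048,
D_in = 2.25, ρ = 1.1, γ = 0.0129, C = −2.89; the `msa_term` component
already carries γ, matching how SIE tables are printed. Both pipelines use
the single-trajectory protocol: receptor and ligand snapshots are the
complex frames, internal energies cancel, and only interaction components
are computed — which is exactly the semantics of the packaged component
tables.

Per-residue decomposition attributes to each receptor residue its atoms'
pairwise electrostatic and van der Waals interactions with the ligand plus
half of the GB cross-terms between its atoms and ligand atoms (the common
50/50 split of a pair term between the two residues involved). The
ele+vdw entries partition the total interaction energy exactly; this
conservation is tested to 1e-8.

## Normal-mode entropy

Toy systems define their internal energy as intra-selection Coulomb + LJ
(1-2 bonded pairs excluded) plus harmonic bonds `E = k/2 (r − r₀)²`, so
the sidecar's `k` is the literal spring constant and a diatomic's
frequency is `(1/2π)·sqrt(k/μ)`. Structures are minimized by repeated
BFGS with analytic gradients to a gradient norm of 1e-8 kcal·mol⁻¹·Å⁻¹;
the Hessian is built by central differences of the analytic gradient
(step 1e-4 Å), mass-weighted, and the rigid-body modes are projected out
via an SVD-orthonormalized basis (which handles the five-mode case of
linear molecules automatically). Remaining negative curvature is an error
— the structure was not at a minimum — reported with the count of
imaginary modes. Entropy is the harmonic-oscillator closed form summed
over modes; −TΔS = −T(S_complex − S_receptor − S_ligand) with each state
minimized independently. Note that this vibrational-only accounting omits
the translational/rotational terms of a full rigid-rotor/harmonic-
oscillator treatment, so toy binding entropies can be favourable.

## Hydrogen bonds

A donor–H⋯acceptor triple qualifies when the donor-heavy to acceptor
distance is strictly below 3.5 Å and the angle at the hydrogen (subtended
by donor heavy atom and acceptor) strictly exceeds 120°; both
inequalities are strict by convention and the two common readings of the
angle coincide at the hydrogen vertex. Donor/acceptor roles come from
topology flags (element inference is too ambiguous for ligands); donor
hydrogens are the bonded hydrogens in the topology bond list. Occupancy is
the percentage of frames in which a triple qualifies; geometry means are
taken over qualifying frames only.

## Synthetic data: what it does and does not show

`make_toy_complex()` builds a deterministic helix-plus-ligand system whose
pairwise energies are hand-computable (the documented 1+1-atom
configuration with ±1 charges at 3.320637 Å gives exactly
−100 kcal/mol of Coulomb energy), optionally with an N–H⋯O pair placed at
an exact requested distance and angle (solved by a 1-D root find; an
unreachable geometry is an error). `sample_correlated_trajectory()` draws
zero-mean Gaussian displacements, independent across axes, with per-axis
atom covariance `D^{1/2} C D^{1/2}` where `C` expands a block-level
correlation design (validated positive semidefinite before sampling); the
normalized cross-correlation of two atoms is then exactly the designed
`C[i,j]` and the expected RMSF is `sqrt(3·variance)`. Generators are
seeded and byte-stable.

These fixtures validate the *estimators* — that DCCM, PCA, RMSF, the
energy terms and occupancies recover known ground truth at stated
tolerances — not the physics of real systems. Gaussian displacement
sampling has no dynamics, anharmonicity, or conformational substates;
toy force fields have no dihedrals or 1-4 terms; and reproducing published
per-complex MD observables (mean RMSDs of 1.1–1.5 Å, principal-component
fractions near 60–70%, specific per-residue energies or occupancies) would
require the original 60-ns solvated trajectories, which are not
redistributable. What the suite demonstrates is that, given trajectories,
every stage computes its quantity correctly.

## Problem sizes and numerical choices

The validation suite is sized for desk-scale runs: correlation and PCA
recoveries use 5000 frames of 10–20 atoms, pipelines use toys of ~20 atoms
over tens of frames, quadrature cross-checks use `integrate()` at 1e-12
relative tolerance. Degenerate inputs are handled by contract: collinear
fit selections, single-frame fluctuation requests, overlapping selections,
non-PSD correlation designs, sub-bond-length hydrogen-bond designs and
unminimized normal-mode inputs are hard errors; zero-variance atoms and
donors without hydrogens are warnings with documented conventions.

## Known limitations

* ΔG^R is a GB surrogate, not a Poisson BEM solution; absolute SIE
  component values on real systems will differ from solver-based ones
  (the affine combination and all recovery properties are unaffected).
* No periodic images, PME, or explicit solvent — end-point analysis of
  isolated complexes only.
* The quasi-harmonic alternative to normal-mode entropy, trajectory
  projection onto PC modes, and energy-based hydrogen-bond scoring are out
  of scope.
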