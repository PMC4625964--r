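# mdbind

Post-processing toolkit, in R, for protein–ligand molecular dynamics (MD)
trajectories: end-point binding free energies, per-residue interaction
decomposition, and the structural-dynamics analyses that usually accompany
them. The package grew out of the analysis of peptide and small-molecule
inhibitors binding the p53 regulator MDMX (MDM4), where two end-point
estimates are compared across four complexes (PMI, pDI, WK23, WW8), but
every function is general: it consumes any multi-model PDB (or plain-text)
trajectory plus a topology sidecar carrying charges, Lennard-Jones and
generalized-Born parameters.

## What it computes

**MM-GBSA.** The binding free energy is assembled from per-snapshot
interaction components of the complex trajectory (single-trajectory
protocol, internal terms cancel):

    ΔG_bind = ΔE_ele + ΔE_vdw + ΔG_pol + ΔG_nonpol − TΔS

* ΔE_ele, ΔE_vdw — gas-phase Coulomb (k_e = 332.0637 kcal·mol⁻¹·Å·e⁻²) and
  12-6 Lennard-Jones interaction between receptor and ligand
  (Lorentz–Berthelot combination, no cutoff);
* ΔG_pol — generalized-Born polar solvation change, using pairwise HCT
  descreening with the OBC tanh rescaling of the effective Born radii;
* ΔG_nonpol = γ·SASA + β (γ = 0.0072 kcal·mol⁻¹·Å⁻², β = 0), with the
  solvent-accessible area from deterministic golden-spiral Shrake–Rupley
  sampling;
* −TΔS — harmonic vibrational entropy from a mass-weighted normal-mode
  analysis at an energy minimum, rigid-body modes projected out.

**SIE.** The solvated interaction energy is the empirical affine score

    ΔG_bind = α·[E_c(D_in) + ΔG_R + E_vdW + γ·ΔMSA(ρ)] + C

with the published calibration α = 0.1048, D_in = 2.25, ρ = 1.1,
γ = 0.0129 kcal·mol⁻¹·Å⁻², C = −2.89 kcal/mol. The reaction-field change
ΔG_R is computed by the same generalized-Born machinery at the interior
dielectric (a documented surrogate for a boundary-element Poisson solver),
and the molecular-surface term uses radii scaled by ρ with a zero probe.

**Structural dynamics.** Kabsch superposition, backbone RMSD series, Cα
RMSF profiles, the normalized dynamic cross-correlation matrix
c_ij = ⟨Δr_i·Δr_j⟩ / (⟨Δr_i²⟩⟨Δr_j²⟩)^{1/2}, and PCA of the 3N×3N
coordinate covariance (eigenvalue spectrum and cumulative fractions).

**Hydrogen bonds.** Geometric occupancy statistics with the strict criteria
donor–acceptor heavy-atom distance < 3.5 Å and angle at the hydrogen
> 120°.

**Synthetic data.** Toy complexes with hand-computable pairwise energies
and designed hydrogen-bond geometry, and Gaussian trajectories with
designed inter-residue correlation blocks — the ground truth against which
every analysis stage is validated.

## Worked example

```r
library(mdbind)

# 1. published component tables -> binding free energies
tab <- load_component_fixtures("mmgbsa")
for (cx in tab$complex) {
  dg <- mmgbsa_combine(mmgbsa_components_from_row(tab[tab$complex == cx, ]))
  cat(sprintf("%-5s dG_bind (MM-GBSA) = %6.1f kcal/mol\n", cx, dg))
}
```

```
PMI   dG_bind (MM-GBSA) =  -13.3 kcal/mol
pDI   dG_bind (MM-GBSA) =  -10.7 kcal/mol
WK23  dG_bind (MM-GBSA) =   -8.4 kcal/mol
WW8   dG_bind (MM-GBSA) =   -8.9 kcal/mol
```

The analogous SIE scores from the packaged SIE table are −10.71, −9.92,
−6.89 and −7.09 kcal/mol. Both methods rank PMI ≻ pDI ≻ WW8/WK23, the
experimental affinity order; van der Waals attraction is the dominant
favourable component in every complex, with the electrostatic attraction
screened away by the polar solvation penalty.

```r
# 2. a synthetic complex through the per-snapshot pipelines
tc <- make_toy_complex(toy_complex_spec(
  n_receptor_residues = 4, atoms_per_residue = 3, ligand_atoms = 3,
  designed_hbond = list(distance = 2.9, angle = 150)))
spec <- correlated_motion_spec(
  blocks = rep(1:2, length.out = tc$topology$n_atoms),
  block_correlations = matrix(c(0.6, -0.3, -0.3, 0.6), 2, 2),
  per_atom_variance = 0.02, n_frames = 100, frame_spacing = 100, seed = 42)
traj <- sample_correlated_trajectory(tc$frame, spec, topology = tc$topology)

mmgbsa_pipeline(traj, tc$topology)
hbond_occupancy(traj, tc$topology)
```

```
MM-GBSA over 100 snapshots (kcal/mol):
  ele        -10.54 +/- 2.10
  vdw          3.65 +/- 3.26
  gpol         9.43 +/- 1.52
  gnonpol     -1.22 +/- 0.02
  -TdS       <none>
  dG_bind      1.32  (enthalpy only)

  donor_label hydrogen_label acceptor_label mean_distance mean_angle occupancy
1     LIG5-N1        LIG5-H1         RES4-O      2.899575    147.513        96
```

The `+/-` column is the per-snapshot dispersion (sample standard deviation
over frames); the hydrogen bond designed at 2.9 Å / 150° persists in 96% of
the jittered frames. `run_full_analysis(run_config(...))` wires all stages
together and writes the full report bundle (RMSD/RMSF/DCCM/PCA tables,
both component tables, decomposition, hydrogen bonds, `summary.json`, a
config echo and a MANIFEST).

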