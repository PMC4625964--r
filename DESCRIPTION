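Package: mdbind
Title: End-Point Binding Free Energies and Structural Dynamics from
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for protein-ligand molecular dynamics
    trajectories. Implements two end-point binding free energy estimators --
    MM-GBSA (gas-phase molecular mechanics plus generalized-Born polar and
    surface-area non-polar solvation, with a normal-mode vibrational entropy
    term) and the empirical solvated interaction energy (SIE) score -- together
    with per-residue energy decomposition, geometric hydrogen-bond occupancy
    statistics, and a structural-dynamics suite (Kabsch superposition, RMSD,
    RMSF, dynamic cross-correlation matrices, and principal component analysis
    of the coordinate covariance). A synthetic-data module generates toy
    complexes and trajectories with known energetic and statistical structure
    so every stage can be validated without an MD engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
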