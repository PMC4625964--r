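# Synthetic systems with known energetic and statistical structure:
# parameterized toy complexes (hand-computable pairwise energies, optional
# designed hydrogen bond), Gaussian trajectories with designed inter-residue
# correlation blocks, and the packaged end-point component tables for the
# four inhibitor-MDMX complexes (PMI, pDI, WK23, WW8).

# run code under a fixed seed without disturbing the caller's RNG stream
#' @keywords internal
#' @noRd
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# element -> (mass, gb_radius, gb_screen)
.ELEMENT_PARAMS <- data.frame(
  element = c("H", "C", "N", "O", "S"),
  mass = c(1.008, 12.011, 14.007, 15.999, 32.06),
  gb_radius = c(1.2, 1.7, 1.55, 1.52, 1.8),
  gb_screen = c(0.85, 0.72, 0.79, 0.85, 0.96),
  stringsAsFactors = FALSE)

#' Specify a toy receptor-ligand complex
#'
#' @param n_receptor_residues number of receptor residues.
#' @param atoms_per_residue atoms per receptor residue.
#' @param ligand_atoms number of ligand atoms.
#' @param charge_pattern numeric vector recycled over receptor then ligand
#'   atoms (elementary charges).
#' @param lj_pattern list with `sigma` (A) and `epsilon` (kcal/mol) vectors,
#'   recycled over all atoms.
#' @param designed_hbond optional list `(distance, angle)`: a donor
#'   N-H (appended to the ligand) and an acceptor O (appended to the
#'   receptor) are placed at exactly this heavy-atom distance (A) and angle
#'   at the hydrogen (degrees).
#' @param ligand_distance distance (A) from the receptor centroid to the
#'   first ligand atom, along +x.
#' @param seed generator seed (recorded; geometry is deterministic).
#' @return An object of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(n_receptor_residues = 3, atoms_per_residue = 3,
                             ligand_atoms = 2,
                             charge_pattern = c(0.2, -0.2),
                             lj_pattern = list(sigma = 3.4, epsilon = 0.1),
                             designed_hbond = NULL,
                             ligand_distance = 6, seed = 1) {
  structure(list(n_receptor_residues = n_receptor_residues,
                 atoms_per_residue = atoms_per_residue,
                 ligand_atoms = ligand_atoms,
                 charge_pattern = charge_pattern, lj_pattern = lj_pattern,
                 designed_hbond = designed_hbond,
                 ligand_distance = ligand_distance, seed = seed),
            class = "toy_complex_spec")
}

# place H between donor D and acceptor A so that |DH| = bond and the
# D-H-A angle equals `angle` degrees; feasible whenever |DA| > bond.
#' @keywords internal
#' @noRd
.place_hydrogen <- function(D, A, angle, bond = 1.0) {
  d <- sqrt(sum((A - D)^2))
  if (d <= bond)
    stop("infeasible designed H-bond geometry: heavy-atom distance ", d,
         " <= donor-H bond length ", bond)
  u <- (A - D) / d
  w <- c(-u[2], u[1], 0)
  if (sqrt(sum(w^2)) < 1e-8) w <- c(1, 0, 0)
  w <- w / sqrt(sum(w^2))
  ang_at_h <- function(beta) {
    H <- D + bond * (cos(beta) * u + sin(beta) * w)
    v1 <- D - H; v2 <- A - H
    acos(min(1, max(-1, sum(v1 * v2) /
                      sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  }
  target <- angle
  f <- function(beta) ang_at_h(beta) - target
  if (f(1e-9) < 0 || f(pi - 1e-6) > 0)
    stop("infeasible designed H-bond geometry: angle ", angle,
         " unreachable at distance ", d)
  beta <- stats::uniroot(f, c(1e-9, pi - 1e-6), tol = 1e-12)$root
  D + bond * (cos(beta) * u + sin(beta) * w)
}

#' Build a toy receptor-ligand complex
#'
#' Receptor atoms are placed deterministically on a helix; ligand atoms sit
#' along +x from the receptor centroid, the first one at exactly
#' `ligand_distance` (so a 1-atom receptor with charge +1 and a 1-atom
#' ligand with charge -1 at 3.320637 A gives a Coulomb energy of exactly
#' -100 kcal/mol at dielectric 1). The optional designed hydrogen bond adds
#' an acceptor oxygen to the receptor and an N-H donor to the ligand at the
#' requested geometry. Output is deterministic: the same spec yields
#' byte-identical files.
#'
#' @param spec a [toy_complex_spec()].
#' @param dir optional directory: when given, `complex.pdb` and
#'   `complex.yaml` (topology sidecar) are written there.
#' @return A list: `topology`, `frame` (N x 3 coordinates), `spec`, and
#'   `paths` (when `dir` was given).
#' @export
make_toy_complex <- function(spec = toy_complex_spec(), dir = NULL) {
  n_rec <- spec$n_receptor_residues * spec$atoms_per_residue
  idx <- seq_len(n_rec)
  rec_xyz <- cbind(5 * cos(0.6 * idx), 5 * sin(0.6 * idx), 0.5 * idx)
  centroid <- colMeans(rec_xyz)
  lig_xyz <- t(vapply(seq_len(spec$ligand_atoms), function(i)
    centroid + c(spec$ligand_distance + 1.5 * (i - 1), 0, 0), numeric(3)))
  rec_res <- rep(seq_len(spec$n_receptor_residues),
                 each = spec$atoms_per_residue)
  n_lig <- spec$ligand_atoms
  element <- rep("C", n_rec + n_lig)
  name <- c(paste0("C", idx), paste0("CL", seq_len(n_lig)))
  res_index <- c(rec_res, rep(spec$n_receptor_residues + 1, n_lig))
  res_name <- c(rep("RES", n_rec), rep("LIG", n_lig))
  chain <- c(rep("A", n_rec), rep("B", n_lig))
  xyz <- rbind(rec_xyz, lig_xyz)
  charges <- rep_len(spec$charge_pattern, n_rec + n_lig)
  donor_flag <- acceptor_flag <- rep(FALSE, n_rec + n_lig)
  bonds <- NULL
  if (!is.null(spec$designed_hbond)) {
    hb <- spec$designed_hbond
    # acceptor O protrudes from the receptor on the -x side of the helix
    # (radius 5 about the z axis); donor N approaches from further out
    A_pos <- c(-8, 0, centroid[3])
    D_pos <- A_pos - c(hb$distance, 0, 0)
    H_pos <- .place_hydrogen(D_pos, A_pos, hb$angle)
    xyz <- rbind(xyz, A_pos, D_pos, H_pos)
    element <- c(element, "O", "N", "H")
    name <- c(name, "O", "N1", "H1")
    res_index <- c(res_index, spec$n_receptor_residues,
                   rep(spec$n_receptor_residues + 1, 2))
    res_name <- c(res_name, "RES", "LIG", "LIG")
    chain <- c(chain, "A", "B", "B")
    charges <- c(charges, -0.45, -0.4, 0.4)
    donor_flag <- c(donor_flag, FALSE, TRUE, FALSE)
    acceptor_flag <- c(acceptor_flag, TRUE, TRUE, FALSE)
    n_at <- length(element)
    bonds <- data.frame(i = n_at - 1, j = n_at, k = 434, r0 = 1.0)
  }
  n_at <- length(element)
  ep <- .ELEMENT_PARAMS[match(element, .ELEMENT_PARAMS$element), ]
  lj_sig <- rep_len(spec$lj_pattern$sigma, n_at)
  lj_eps <- rep_len(spec$lj_pattern$epsilon, n_at)
  if (!is.null(spec$designed_hbond)) {
    # element-appropriate LJ for the O/N/H hydrogen-bond trio so the
    # designed contact geometry is not a steric clash under the pattern LJ
    trio <- (n_at - 2):n_at
    lj_sig[trio] <- c(2.96, 3.25, 1.07)
    lj_eps[trio] <- c(0.21, 0.17, 0.016)
  }
  atoms <- data.frame(
    serial = seq_len(n_at), name = name, element = element,
    residue_index = res_index, residue_name = res_name, chain_id = chain,
    charge = charges,
    lj_sigma = lj_sig,
    lj_epsilon = lj_eps,
    gb_radius = ep$gb_radius, gb_screen = ep$gb_screen, mass = ep$mass,
    is_donor_heavy = donor_flag, is_acceptor = acceptor_flag,
    stringsAsFactors = FALSE)
  receptor <- which(chain == "A")
  ligand <- which(chain == "B")
  top <- topology(atoms, receptor = receptor, ligand = ligand, bonds = bonds)
  out <- list(topology = top, frame = unname(as.matrix(xyz)), spec = spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    pdb_path <- file.path(dir, "complex.pdb")
    sidecar_path <- file.path(dir, "complex.yaml")
    write_pdb_models(trajectory(out$frame, topology = top), pdb_path,
                     topology = top)
    write_topology_sidecar(top, sidecar_path)
    out$paths <- c(pdb = pdb_path, sidecar = sidecar_path)
  }
  out
}

#' Specify a correlated-motion Gaussian trajectory
#'
#' Displacements are zero-mean Gaussian, independent across the x/y/z axes,
#' with per-axis atom covariance `S = D^{1/2} C D^{1/2}` where
#' `C[i,j] = block_correlations[b_i, b_j]` (unit diagonal) and `D` carries
#' the per-atom, per-axis variances. The normalized cross-correlation of
#' atoms i and j (summed over axes) is then exactly `C[i,j]`, and the
#' expected RMSF of atom i is `sqrt(3 * variance_i)`.
#'
#' @param blocks integer vector assigning each atom to a block.
#' @param block_correlations symmetric B x B matrix of target correlations
#'   (diagonal = within-block correlation between distinct atoms).
#' @param per_atom_variance per-axis displacement variance (A^2), recycled
#'   over atoms.
#' @param n_frames number of frames.
#' @param frame_spacing frame spacing in ps.
#' @param seed RNG seed.
#' @return An object of class `correlated_motion_spec`.
#' @export
correlated_motion_spec <- function(blocks, block_correlations,
                                   per_atom_variance = 0.09,
                                   n_frames = 1000, frame_spacing = 10,
                                   seed = 1) {
  B <- max(blocks)
  R <- as.matrix(block_correlations)
  stopifnot(nrow(R) == B, ncol(R) == B, all(abs(R) <= 1),
            isTRUE(all.equal(R, t(R))))
  structure(list(blocks = as.integer(blocks), block_correlations = R,
                 per_atom_variance = per_atom_variance,
                 n_frames = as.integer(n_frames),
                 frame_spacing = frame_spacing, seed = seed),
            class = "correlated_motion_spec")
}

#' Sample a Gaussian trajectory with designed correlation structure
#'
#' Frames are `reference + displacement`, with displacements drawn from the
#' zero-mean Gaussian design of the spec (see [correlated_motion_spec()]).
#' The implied atom correlation matrix is validated to be positive
#' semidefinite before sampling; a non-PSD design aborts with the offending
#' eigenvalue. Reproducible under the spec's seed.
#'
#' @param reference N x 3 reference coordinates (Angstrom).
#' @param spec a [correlated_motion_spec()].
#' @param topology optional [topology()] attached to the result.
#' @return A [trajectory()] with `n_frames` frames spaced `frame_spacing`
#'   ps.
#' @export
sample_correlated_trajectory <- function(reference, spec, topology = NULL) {
  n <- nrow(reference)
  stopifnot(length(spec$blocks) == n)
  C <- spec$block_correlations[spec$blocks, spec$blocks]
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-10)
    stop("designed correlation matrix is not positive semidefinite ",
         "(eigenvalue ", format(min(ev$values)), ")")
  lam <- pmax(ev$values, 0)
  sdev <- sqrt(rep_len(spec$per_atom_variance, n))
  # per-axis covariance sqrt: D^{1/2} U Lam^{1/2}
  A <- (sdev * ev$vectors) %*% diag(sqrt(lam))
  nf <- spec$n_frames
  xyz <- .with_seed(spec$seed, {
    out <- matrix(0, nf, 3 * n)
    for (ax in 1:3) {
      Z <- matrix(stats::rnorm(nf * n), nf, n)
      disp <- Z %*% t(A)
      out[, seq(ax, 3 * n, by = 3)] <-
        disp + matrix(reference[, ax], nf, n, byrow = TRUE)
    }
    out
  })
  trajectory(xyz, times = spec$frame_spacing * seq_len(nf),
             topology = topology)
}

# ---------------------------------------------------------------------------
# Packaged end-point component tables (four inhibitor-MDMX complexes)

#' @keywords internal
#' @noRd
.mmgbsa_component_table <- function() {
  data.frame(
    complex = c("PMI", "pDI", "WK23", "WW8"),
    dE_ele = c(-136.2, -141.9, -32.9, -53.1),
    dE_ele_sd = c(7.6, 8.4, 6.4, 6.8),
    dE_vdw = c(-64.8, -55.1, -36.0, -37.1),
    dE_vdw_sd = c(2.1, 2.1, 1.9, 1.4),
    dG_nonpol = c(-9.5, -8.5, -5.1, -5.5),
    dG_nonpol_sd = c(0.1, 0.3, 0.1, 0.2),
    dG_pol = c(158.3, 161.9, 46.7, 67.1),
    dG_pol_sd = c(8.7, 10.2, 6.8, 7.2),
    minus_TdS = c(38.9, 32.9, 18.9, 19.7),
    minus_TdS_sd = c(1.2, 1.6, 1.1, 1.5),
    dG_bind = c(-13.3, -10.7, -8.4, -8.9),
    dG_exp = c(-10.1, -8.5, -6.1, -6.8),
    stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
.sie_component_table <- function() {
  data.frame(
    complex = c("PMI", "pDI", "WK23", "WW8"),
    dE_vdW = c(-61.11, -58.54, -36.57, -37.82),
    dE_vdW_sd = c(2.08, 2.41, 1.11, 1.44),
    dE_c = c(-64.99, -66.67, -15.84, -21.58),
    dE_c_sd = c(7.48, 9.82, 2.87, 3.68),
    gamma_dMSA = c(-11.67, -10.84, -6.29, -6.91),
    gamma_dMSA_sd = c(0.58, 0.61, 0.12, 0.42),
    dG_R = c(63.13, 68.98, 20.52, 26.23),
    dG_R_sd = c(6.73, 7.53, 3.05, 3.45),
    C = c(-2.89, -2.89, -2.89, -2.89),
    C_sd = c(0, 0, 0, 0),
    dG_bind = c(-10.71, -9.92, -6.89, -7.09),
    dG_bind_sd = c(0.47, 1.97, 0.30, 3.54),
    stringsAsFactors = FALSE)
}

#' @keywords internal
#' @noRd
.hbond_reference_table <- function() {
  data.frame(
    complex = c("PMI", "pDI", "WK23", "WW8"),
    donor = c("Trp7'-NE1-HE1", "Trp7'-NE1-HE1", "WK23-N11-H4", "WW8-N8-H3"),
    acceptor = c("Met53-O", "Met53-O", "Met53-O", "Met53-O"),
    distance = c(2.83, 2.91, 2.83, 2.92),
    angle = c(149.25, 138.53, 157.25, 146.35),
    occupancy = c(92.31, 90.02, 97.04, 79.24),
    stringsAsFactors = FALSE)
}

#' Write the packaged component tables to disk
#'
#' Writes three tab-delimited fixtures with the end-point energy components
#' and hydrogen-bond geometries of the four inhibitor-MDMX complexes
#' (values as printed, one row per complex): `mmgbsa_components.tsv`,
#' `sie_components.tsv`, `hbond_reference.tsv`. Output is byte-stable
#' across runs.
#'
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
make_component_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(mmgbsa = file.path(dir, "mmgbsa_components.tsv"),
             sie = file.path(dir, "sie_components.tsv"),
             hbonds = file.path(dir, "hbond_reference.tsv"))
  tables <- list(.mmgbsa_component_table(), .sie_component_table(),
                 .hbond_reference_table())
  for (k in 1:3)
    utils::write.table(tables[[k]], paths[k], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  invisible(paths)
}

#' Load a packaged component table
#'
#' @param which one of `"mmgbsa"`, `"sie"`, `"hbonds"`.
#' @param dir directory holding the fixtures; defaults to the copies
#'   installed with the package.
#' @return the table as a data frame.
#' @export
load_component_fixtures <- function(which = c("mmgbsa", "sie", "hbonds"),
                                    dir = NULL) {
  which <- match.arg(which)
  fname <- c(mmgbsa = "mmgbsa_components.tsv", sie = "sie_components.tsv",
             hbonds = "hbond_reference.tsv")[which]
  path <- if (is.null(dir))
    system.file("extdata", fname, package = "mdbind", mustWork = TRUE)
  else file.path(dir, fname)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Convert a component-table row to energy components
#'
#' Maps one row of the packaged MM-GBSA table to an [energy_components()],
#' or of the SIE table to a [sie_components()].
#'
#' @param row single-row data frame from [load_component_fixtures()].
#' @return an [energy_components()] or [sie_components()].
#' @export
mmgbsa_components_from_row <- function(row) {
  energy_components(ele = row$dE_ele, vdw = row$dE_vdw, gpol = row$dG_pol,
                    gnonpol = row$dG_nonpol, minus_T_dS = row$minus_TdS)
}

#' @rdname mmgbsa_components_from_row
#' @export
sie_components_from_row <- function(row) {
  sie_components(coulomb_Din = row$dE_c, vdw = row$dE_vdW,
                 reaction_field = row$dG_R, msa_term = row$gamma_dMSA)
}
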