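# Pairwise molecular-mechanics interaction energies between disjoint atom
# selections: Coulomb and 12-6 Lennard-Jones (Lorentz-Berthelot combination).
# No non-bonded cutoff by default: end-point rescoring operates on isolated
# complexes, unlike the MD engine that produced the frames. 1-2/1-3/1-4
# exclusions never arise because the two selections are disjoint molecules.

#' @keywords internal
#' @noRd
.pair_distances <- function(coords, set_a, set_b) {
  A <- coords[set_a, , drop = FALSE]
  B <- coords[set_b, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' @keywords internal
#' @noRd
.check_sets <- function(set_a, set_b) {
  if (length(intersect(set_a, set_b)))
    stop("selections must be disjoint")
  if (!length(set_a) || !length(set_b)) stop("empty selection")
}

# Per-pair Coulomb energies, |set_a| x |set_b| matrix.
#' @keywords internal
#' @noRd
.coulomb_pair_matrix <- function(coords, top, set_a, set_b, dielectric = 1,
                                 cutoff = Inf) {
  r <- .pair_distances(coords, set_a, set_b)
  if (any(r < 1e-6)) stop("overlapping atoms (r < 1e-6 A) between selections")
  qq <- tcrossprod(top$atoms$charge[set_a], top$atoms$charge[set_b])
  e <- .const$k_e * qq / (dielectric * r)
  if (is.finite(cutoff)) e[r > cutoff] <- 0
  e
}

# Per-pair Lennard-Jones energies, |set_a| x |set_b| matrix.
#' @keywords internal
#' @noRd
.lj_pair_matrix <- function(coords, top, set_a, set_b, cutoff = Inf) {
  r <- .pair_distances(coords, set_a, set_b)
  if (any(r < 1e-6)) stop("overlapping atoms (r < 1e-6 A) between selections")
  sig <- outer(top$atoms$lj_sigma[set_a], top$atoms$lj_sigma[set_b], `+`) / 2
  eps <- sqrt(tcrossprod(top$atoms$lj_epsilon[set_a],
                         top$atoms$lj_epsilon[set_b]))
  sr6 <- (sig / r)^6
  e <- 4 * eps * (sr6^2 - sr6)
  if (is.finite(cutoff)) e[r > cutoff] <- 0
  e
}

#' Coulomb interaction energy between two selections
#'
#' `sum_{i in a, j in b} k_e q_i q_j / (dielectric * r_ij)` with
#' `k_e = 332.0637` kcal mol^-1 A e^-2 (AMBER convention). With a uniform
#' interior dielectric D_in this is the intermolecular Coulomb term of the
#' SIE score; with dielectric 1 it is the gas-phase electrostatic term of
#' MM-GBSA.
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param top a [topology()] supplying charges.
#' @param set_a,set_b disjoint atom index vectors.
#' @param dielectric uniform screening dielectric (> 0, default 1).
#' @param cutoff optional distance cutoff in Angstrom (default `Inf`: none).
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(coords, top, set_a = top$receptor,
                           set_b = top$ligand, dielectric = 1,
                           cutoff = Inf) {
  .check_sets(set_a, set_b)
  stopifnot(dielectric > 0)
  sum(.coulomb_pair_matrix(coords, top, set_a, set_b, dielectric, cutoff))
}

#' Lennard-Jones interaction energy between two selections
#'
#' `sum 4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ]` with Lorentz-Berthelot
#' combination: `sig_ij` the arithmetic mean of the atomic sigmas, `eps_ij`
#' the geometric mean of the epsilons.
#'
#' @inheritParams coulomb_energy
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(coords, top, set_a = top$receptor, set_b = top$ligand,
                      cutoff = Inf) {
  .check_sets(set_a, set_b)
  sum(.lj_pair_matrix(coords, top, set_a, set_b, cutoff))
}

#' Per-frame interaction energy series with mean and dispersion
#'
#' Evaluates the Coulomb and Lennard-Jones interaction between the two
#' selections for every frame and summarizes each component with its mean
#' and the snapshot dispersion `sqrt(sum (x_i - xbar)^2 / (N - 1))` (the
#' sample standard deviation over snapshots, the convention used when
#' end-point component tables quote "standard errors").
#'
#' @param traj a [trajectory()].
#' @param top a [topology()].
#' @param set_a,set_b disjoint atom index vectors (default: receptor and
#'   ligand selections of `top`).
#' @param dielectric Coulomb screening dielectric.
#' @return A list of class `energy_series`: data frame `per_frame` (columns
#'   `time`, `ele`, `vdw`), plus `mean` and `sd` named vectors.
#' @export
interaction_energy_series <- function(traj, top, set_a = top$receptor,
                                      set_b = top$ligand, dielectric = 1) {
  nf <- n_frames(traj)
  if (nf < 1) stop("trajectory has no frames")
  ele <- numeric(nf); vdw <- numeric(nf)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    ele[f] <- coulomb_energy(co, top, set_a, set_b, dielectric)
    vdw[f] <- lj_energy(co, top, set_a, set_b)
  }
  structure(list(
    per_frame = data.frame(time = traj$times, ele = ele, vdw = vdw),
    mean = c(ele = mean(ele), vdw = mean(vdw)),
    sd = c(ele = snapshot_sd(ele), vdw = snapshot_sd(vdw))),
    class = "energy_series")
}

#' Snapshot dispersion statistic
#'
#' The sample standard deviation `sqrt(sum (x_i - xbar)^2 / (N - 1))` used
#' to annotate per-snapshot energy components; 0 for a single snapshot.
#'
#' @param x numeric vector of per-snapshot values.
#' @return dispersion in the units of `x`.
#' @export
snapshot_sd <- function(x) {
  if (length(x) < 2) return(0)
  sqrt(sum((x - mean(x))^2) / (length(x) - 1))
}
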