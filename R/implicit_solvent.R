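# Generalized Born polar solvation (pairwise HCT descreening with OBC tanh
# rescaling), deterministic Shrake-Rupley solvent-accessible surface areas,
# and the binding-induced area change used by the surface-area energy terms.

# HCT pairwise descreening integral of atom j (scaled reduced radius sr2)
# against atom i (reduced radius or1) at distance r:
#   I_j = (1/4pi) * integral over the scaled sphere of j, outside the ball
#         of radius or1 around i, of |x - x_i|^-4 dV.
#' @keywords internal
#' @noRd
.hct_integral <- function(r, or1, sr2) {
  if (r + sr2 <= or1) return(0)
  U <- r + sr2
  L <- max(or1, abs(r - sr2))
  term <- 1 / L - 1 / U + 0.25 * (r - sr2^2 / r) * (1 / U^2 - 1 / L^2) +
    0.5 * log(L / U) / r
  if (sr2 - r > or1) term <- term + 2 * (1 / or1 - 1 / L)
  0.5 * term
}

#' Effective Born radii (OBC)
#'
#' Computes per-atom effective Born radii by pairwise HCT descreening with
#' the OBC tanh rescaling: with reduced radius `rho_i~ = rho_i - offset`,
#' descreening integral `I_i` and `psi = I_i * rho_i~`,
#' `1/R_i = 1/rho_i~ - tanh(a psi - b psi^2 + g psi^3) / rho_i`.
#' An isolated atom (zero descreening) has `R_i = rho_i - offset`.
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param top a [topology()] supplying `gb_radius` (intrinsic radii) and
#'   `gb_screen` (descreening scales).
#' @param selection atom indices defining the solute (default: all atoms);
#'   radii are computed in the context of this selection only.
#' @param params a [gb_params()].
#' @return numeric vector of effective radii (Angstrom) for `selection`.
#' @export
effective_born_radii <- function(coords, top, selection = NULL,
                                 params = gb_params()) {
  selection <- selection %||% seq_len(top$n_atoms)
  rho <- top$atoms$gb_radius[selection]
  scr <- top$atoms$gb_screen[selection]
  red <- rho - params$radius_offset
  if (any(red <= 0))
    stop("non-positive reduced radius (gb_radius <= radius_offset)")
  co <- coords[selection, , drop = FALSE]
  n <- length(selection)
  R <- numeric(n)
  d <- as.matrix(stats::dist(co))
  for (i in seq_len(n)) {
    I <- 0
    for (j in seq_len(n)[-i])
      I <- I + .hct_integral(d[i, j], red[i], scr[j] * red[j])
    psi <- I * red[i]
    tanh_arg <- params$obc_alpha * psi - params$obc_beta * psi^2 +
      params$obc_gamma * psi^3
    R[i] <- 1 / (1 / red[i] - tanh(tanh_arg) / rho[i])
  }
  R
}

# Pairwise GB energy matrix (upper structure not exploited; small systems).
# E_ij contribution uses f_GB = sqrt(r^2 + Ri Rj exp(-r^2 / (4 Ri Rj))).
#' @keywords internal
#' @noRd
.gb_energy_matrix <- function(coords, charges, radii, params) {
  pref <- -0.5 * .const$k_e *
    (1 / params$interior_dielectric - 1 / params$exterior_dielectric)
  co <- coords
  d2 <- as.matrix(stats::dist(co))^2
  RR <- tcrossprod(radii)
  fgb <- sqrt(d2 + RR * exp(-d2 / (4 * RR)))
  qq <- tcrossprod(charges)
  pref * qq / fgb   # diagonal: fgb = R_i, the Born self-term
}

#' Generalized Born polar solvation energy
#'
#' `G_pol = -k_e/2 (1/e_in - 1/e_out) sum_ij q_i q_j / f_GB(r_ij, R_i, R_j)`
#' including the i = j Born self-terms. For a single ion of charge q and
#' effective radius a this reduces to the Born formula
#' `-k_e q^2 (1/e_in - 1/e_out) / (2a)`.
#'
#' @inheritParams effective_born_radii
#' @param radii optional precomputed effective radii for `selection`.
#' @return energy in kcal/mol.
#' @export
gb_polar_energy <- function(coords, top, selection = NULL,
                            params = gb_params(), radii = NULL) {
  selection <- selection %||% seq_len(top$n_atoms)
  if (is.null(radii))
    radii <- effective_born_radii(coords, top, selection, params)
  E <- .gb_energy_matrix(coords[selection, , drop = FALSE],
                         top$atoms$charge[selection], radii, params)
  sum(E)
}

#' Polar solvation change upon binding
#'
#' Single-trajectory end-point convention: from one complex frame,
#' `dG_pol = G_pol(complex) - G_pol(receptor) - G_pol(ligand)`, with
#' effective radii recomputed for each state from the same coordinates
#' (the separated states lose the partner's descreening).
#'
#' @param coords N x 3 complex coordinates (Angstrom).
#' @param top a [topology()] with receptor/ligand selections.
#' @param params a [gb_params()].
#' @return energy change in kcal/mol.
#' @export
delta_gpol_binding <- function(coords, top, params = gb_params()) {
  cplx <- c(top$receptor, top$ligand)
  gb_polar_energy(coords, top, cplx, params) -
    gb_polar_energy(coords, top, top$receptor, params) -
    gb_polar_energy(coords, top, top$ligand, params)
}

#' Deterministic golden-spiral points on the unit sphere
#' @param n number of points (>= 12).
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  stopifnot(n >= 12)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  s <- sqrt(pmax(1 - z^2, 0))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples each atom's solvent-accessible sphere (radius
#' `radius_scale * gb_radius + probe_radius`) with a deterministic golden
#' spiral; a point is accessible when outside every other atom's sphere.
#' Deterministic for a fixed point count (no randomness).
#'
#' @param coords N x 3 coordinate matrix (Angstrom).
#' @param top a [topology()] supplying atomic radii via `gb_radius`.
#' @param selection atom indices defining the solute (default: all).
#' @param params a [surface_params()].
#' @return A list: `total` (A^2) and `per_atom` (A^2, one entry per
#'   selection atom; sums to `total`).
#' @export
sasa <- function(coords, top, selection = NULL, params = surface_params()) {
  selection <- selection %||% seq_len(top$n_atoms)
  co <- coords[selection, , drop = FALSE]
  rad <- params$radius_scale * top$atoms$gb_radius[selection] +
    params$probe_radius
  n <- length(selection)
  pts <- golden_spiral_points(params$n_sphere_points)
  d <- as.matrix(stats::dist(co))
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < rad[i] + rad & seq_len(n) != i)
    p <- sweep(pts * rad[i], 2, co[i, ], `+`)
    acc <- rep(TRUE, nrow(p))
    for (j in nb) {
      dj2 <- (p[, 1] - co[j, 1])^2 + (p[, 2] - co[j, 2])^2 +
        (p[, 3] - co[j, 3])^2
      acc <- acc & dj2 > rad[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * rad[i]^2 * mean(acc)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Binding-induced surface-area change
#'
#' `dA = area(complex) - area(receptor) - area(ligand)` on the same frame,
#' with all atomic radii scaled by `params$radius_scale`. With `rho = 1.1`
#' and a zero probe this is the molecular-surface-area change entering the
#' SIE hydrophobic term; with `rho = 1` and a 1.4 A probe it is the plain
#' SASA change of the non-polar MM-GBSA term. Negative for bound poses in
#' contact (surface is buried).
#'
#' @param coords N x 3 complex coordinates (Angstrom).
#' @param top a [topology()] with receptor/ligand selections.
#' @param params a [surface_params()].
#' @return area change in A^2.
#' @export
delta_msa <- function(coords, top, params = surface_params()) {
  cplx <- c(top$receptor, top$ligand)
  sasa(coords, top, cplx, params)$total -
    sasa(coords, top, top$receptor, params)$total -
    sasa(coords, top, top$ligand, params)$total
}
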