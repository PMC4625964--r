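# Physical constants and frozen model parameter sets.
# Single unit system throughout the package: lengths in Angstrom, times in ps,
# energies in kcal/mol, charges in elementary-charge units, masses in amu.

#' @keywords internal
#' @noRd
.const <- list(
  # Coulomb constant, AMBER convention, kcal mol^-1 A e^-2
  k_e = 332.0637,
  # gas constant, kcal mol^-1 K^-1
  R_gas = 1.98720425864083e-3,
  # conversion: (kcal mol^-1 A^-2 amu^-1) -> rad^2 s^-2 for omega^2.
  # 1 kcal/mol = 4184/N_A J; 1 A^-2 = 1e20 m^-2; 1 amu^-1 = 1/1.66053906660e-27 kg^-1
  omega2_SI = 4184 * 1e20 / (6.02214076e23 * 1.66053906660e-27),
  # h*nu/kT = hbar*omega/(kB*T): hbar/kB in K*s
  hbar_over_kB = 1.054571817e-34 / 1.380649e-23
)

#' Generalized Born (OBC) model parameters
#'
#' Parameter container for the pairwise-descreening generalized Born model
#' with tanh rescaling of the reduced descreening integral (the "modified GB
#' model" of Onufriev, Bashford and Case). The default shape constants
#' `(0.8, 0, 2.909125)` are the OBC model I set; model II `(1.0, 0.8, 4.85)`
#' can be selected via `variant = "II"`.
#'
#' @param interior_dielectric solute interior dielectric (dimensionless, > 0).
#' @param exterior_dielectric solvent dielectric (default 78.5).
#' @param obc_alpha,obc_beta,obc_gamma tanh-rescaling shape constants.
#' @param radius_offset intrinsic-radius offset in Angstrom (default 0.09).
#' @param variant shortcut selecting a published constant set, `"I"` or `"II"`;
#'   ignored when the three shape constants are given explicitly.
#' @return An object of class `gb_params`.
#' @export
gb_params <- function(interior_dielectric = 1,
                      exterior_dielectric = 78.5,
                      obc_alpha = NULL, obc_beta = NULL, obc_gamma = NULL,
                      radius_offset = 0.09,
                      variant = c("I", "II")) {
  variant <- match.arg(variant)
  set <- if (variant == "I") c(0.8, 0, 2.909125) else c(1.0, 0.8, 4.85)
  p <- list(
    interior_dielectric = interior_dielectric,
    exterior_dielectric = exterior_dielectric,
    obc_alpha  = if (is.null(obc_alpha))  set[1] else obc_alpha,
    obc_beta   = if (is.null(obc_beta))   set[2] else obc_beta,
    obc_gamma  = if (is.null(obc_gamma))  set[3] else obc_gamma,
    radius_offset = radius_offset
  )
  stopifnot(p$interior_dielectric > 0, p$exterior_dielectric > p$interior_dielectric)
  structure(p, class = "gb_params")
}

#' Surface-area calculation parameters
#'
#' Controls the deterministic Shrake-Rupley sphere sampling. `radius_scale`
#' is the variable-radius factor rho applied to all atomic radii before adding
#' the probe; the SIE molecular-surface term uses rho = 1.1 with a zero probe,
#' whereas a conventional solvent-accessible area uses rho = 1 with a 1.4 A
#' probe.
#'
#' @param probe_radius solvent probe radius in Angstrom (>= 0, default 1.4).
#' @param n_sphere_points number of golden-spiral sample points per atom
#'   (>= 12, default 960).
#' @param radius_scale dimensionless atomic-radius scale rho (default 1.1).
#' @return An object of class `surface_params`.
#' @export
surface_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                           radius_scale = 1.1) {
  stopifnot(probe_radius >= 0, n_sphere_points >= 12, radius_scale > 0)
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radius_scale = radius_scale),
            class = "surface_params")
}

#' Empirical coefficients of the solvated interaction energy score
#'
#' The five fitted coefficients of the SIE scoring function
#' `dG = alpha * (E_c(D_in) + dG_R + E_vdW + gamma * dMSA(rho)) + C`.
#' Defaults are the published calibration: alpha = 0.1048, D_in = 2.25,
#' rho = 1.1, gamma = 0.0129 kcal mol^-1 A^-2, C = -2.89 kcal/mol.
#'
#' @param alpha global proportionality coefficient (dimensionless).
#' @param interior_dielectric solute interior dielectric D_in.
#' @param rho atomic-radius scale for the molecular surface term.
#' @param gamma_msa surface coefficient, kcal mol^-1 A^-2.
#' @param constant_C additive constant, kcal/mol.
#' @return An object of class `sie_params`.
#' @export
sie_params <- function(alpha = 0.1048, interior_dielectric = 2.25,
                       rho = 1.1, gamma_msa = 0.0129, constant_C = -2.89) {
  structure(list(alpha = alpha, interior_dielectric = interior_dielectric,
                 rho = rho, gamma_msa = gamma_msa, constant_C = constant_C),
            class = "sie_params")
}

#' Non-polar solvation parameters
#'
#' Coefficients of the empirical surface-area relation
#' `G_nonpol = gamma * SASA + beta`. Defaults: gamma = 0.0072
#' kcal mol^-1 A^-2, beta = 0 kcal/mol.
#'
#' @param gamma surface tension coefficient, kcal mol^-1 A^-2.
#' @param beta additive constant, kcal/mol.
#' @return An object of class `nonpolar_params`.
#' @export
nonpolar_params <- function(gamma = 0.0072, beta = 0) {
  structure(list(gamma = gamma, beta = beta), class = "nonpolar_params")
}

#' Geometric hydrogen-bond criteria
#'
#' A donor-H...acceptor triple qualifies when the donor-heavy-atom to
#' acceptor distance is strictly less than `max_heavy_distance` and the angle
#' at the hydrogen (subtended by donor heavy atom and acceptor) is strictly
#' greater than `min_angle`.
#'
#' @param max_heavy_distance heavy-atom distance cutoff in Angstrom
#'   (default 3.5).
#' @param min_angle angle cutoff in degrees (default 120).
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_heavy_distance = 3.5, min_angle = 120) {
  stopifnot(max_heavy_distance > 0, min_angle > 0, min_angle <= 180)
  structure(list(max_heavy_distance = max_heavy_distance,
                 min_angle = min_angle),
            class = "hbond_criteria")
}
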