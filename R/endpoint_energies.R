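# End-point binding free energy assembly: the MM-GBSA combination
#   dG = dE_ele + dE_vdw + dG_pol + dG_nonpol - T dS
# and the empirical SIE score
#   dG = alpha * (E_c(D_in) + dG_R + E_vdW + gamma * dMSA(rho)) + C,
# plus the per-snapshot pipelines that produce their components from a
# complex trajectory (single-trajectory protocol: receptor and ligand states
# are taken from the complex frames, so internal terms cancel and only
# interaction components are evaluated), and per-residue decomposition.

#' Bundle MM-GBSA energy components
#'
#' @param ele,vdw gas-phase electrostatic and van der Waals interaction
#'   energies, kcal/mol.
#' @param gpol,gnonpol polar and non-polar solvation changes, kcal/mol.
#' @param minus_T_dS entropy penalty stored as the signed quantity `-T dS`
#'   (positive for a binding penalty), kcal/mol; `NA` until computed.
#' @return A list of class `energy_components`.
#' @export
energy_components <- function(ele, vdw, gpol, gnonpol, minus_T_dS = NA_real_) {
  stopifnot(is.finite(ele), is.finite(vdw), is.finite(gpol),
            is.finite(gnonpol))
  structure(list(ele = ele, vdw = vdw, gpol = gpol, gnonpol = gnonpol,
                 minus_T_dS = minus_T_dS),
            class = "energy_components")
}

#' Combine MM-GBSA components into a binding free energy
#'
#' Exact sum `ele + vdw + gpol + gnonpol + (-T dS)`. When the entropy field
#' is missing (`NA`), the enthalpy-only estimate is returned with attribute
#' `entropy_included = FALSE` and a warning.
#'
#' @param components an [energy_components()] (or a list with the same
#'   fields).
#' @return binding free energy, kcal/mol.
#' @export
mmgbsa_combine <- function(components) {
  g <- components$ele + components$vdw + components$gpol + components$gnonpol
  if (is.null(components$minus_T_dS) || is.na(components$minus_T_dS)) {
    warning("entropy term missing: returning enthalpy-only estimate")
    return(structure(g, entropy_included = FALSE))
  }
  structure(g + components$minus_T_dS, entropy_included = TRUE)
}

#' Bundle SIE energy components
#'
#' @param coulomb_Din intermolecular Coulomb energy at the interior
#'   dielectric D_in (E_c), kcal/mol.
#' @param vdw van der Waals interaction energy (E_vdW), kcal/mol.
#' @param reaction_field reaction-field (polar solvation) change upon
#'   binding (dG_R), kcal/mol.
#' @param msa_term surface term `gamma * dMSA(rho)`, already multiplied by
#'   gamma, kcal/mol.
#' @return A list of class `sie_components`.
#' @export
sie_components <- function(coulomb_Din, vdw, reaction_field, msa_term) {
  stopifnot(is.finite(coulomb_Din), is.finite(vdw), is.finite(reaction_field),
            is.finite(msa_term))
  structure(list(coulomb_Din = coulomb_Din, vdw = vdw,
                 reaction_field = reaction_field, msa_term = msa_term),
            class = "sie_components")
}

#' Solvated interaction energy score
#'
#' `dG = alpha * (E_c + dG_R + E_vdW + gamma_dMSA) + C`; the `msa_term`
#' field already carries the gamma factor, matching how SIE component tables
#' are printed.
#'
#' @param components a [sie_components()].
#' @param params a [sie_params()].
#' @return binding free energy, kcal/mol.
#' @export
sie_score <- function(components, params = sie_params()) {
  params$alpha * (components$coulomb_Din + components$reaction_field +
                    components$vdw + components$msa_term) +
    params$constant_C
}

#' Surface-area non-polar solvation energy
#'
#' `G_nonpol = gamma * SASA + beta`; applied to an area difference it gives
#' the non-polar binding term.
#'
#' @param sasa_value surface area (or area change), A^2.
#' @param params a [nonpolar_params()].
#' @return energy in kcal/mol.
#' @export
nonpolar_energy <- function(sasa_value, params = nonpolar_params()) {
  params$gamma * sasa_value + params$beta
}

#' MM-GBSA per-snapshot pipeline
#'
#' For each selected frame of a complex trajectory: gas-phase electrostatic
#' and van der Waals interaction energies (dielectric 1), the generalized
#' Born polar solvation change, and the non-polar term from the
#' binding-induced SASA change (unscaled radii, 1.4 A probe). Components are
#' summarized by their mean and snapshot dispersion (sample standard
#' deviation), and combined into the binding free energy; a normal-mode
#' `-T dS` may be attached.
#'
#' @param traj a complex [trajectory()].
#' @param top a [topology()] with receptor/ligand selections.
#' @param frame_sel optional [frame_selection()] applied first.
#' @param gb a [gb_params()] (interior dielectric 1 by convention).
#' @param np a [nonpolar_params()].
#' @param surface a [surface_params()] for the SASA difference; default
#'   probe 1.4 A, unscaled radii.
#' @param minus_T_dS optional entropy penalty, kcal/mol.
#' @return A list of class `mmgbsa_result`: `per_frame` data frame (`time`,
#'   `ele`, `vdw`, `gpol`, `gnonpol`), `mean`, `sd`, `components` (mean
#'   [energy_components()]), and `dG` (kcal/mol; see [mmgbsa_combine()]).
#' @export
mmgbsa_pipeline <- function(traj, top, frame_sel = NULL, gb = gb_params(),
                            np = nonpolar_params(),
                            surface = surface_params(radius_scale = 1),
                            minus_T_dS = NA_real_) {
  if (!is.null(frame_sel)) traj <- select_frames(traj, frame_sel)
  nf <- n_frames(traj)
  ele <- vdw <- gpol <- gnonpol <- numeric(nf)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    ele[f] <- coulomb_energy(co, top, dielectric = 1)
    vdw[f] <- lj_energy(co, top)
    gpol[f] <- delta_gpol_binding(co, top, gb)
    gnonpol[f] <- nonpolar_energy(delta_msa(co, top, surface), np)
  }
  per_frame <- data.frame(time = traj$times, ele = ele, vdw = vdw,
                          gpol = gpol, gnonpol = gnonpol)
  mn <- c(ele = mean(ele), vdw = mean(vdw), gpol = mean(gpol),
          gnonpol = mean(gnonpol))
  sdv <- c(ele = snapshot_sd(ele), vdw = snapshot_sd(vdw),
           gpol = snapshot_sd(gpol), gnonpol = snapshot_sd(gnonpol))
  comp <- energy_components(mn["ele"], mn["vdw"], mn["gpol"], mn["gnonpol"],
                            minus_T_dS)
  dG <- if (is.na(minus_T_dS)) suppressWarnings(mmgbsa_combine(comp))
        else mmgbsa_combine(comp)
  structure(list(per_frame = per_frame, mean = mn, sd = sdv,
                 components = comp, dG = as.numeric(dG),
                 entropy_included = attr(dG, "entropy_included")),
            class = "mmgbsa_result")
}

#' @export
print.mmgbsa_result <- function(x, ...) {
  cat("MM-GBSA over", nrow(x$per_frame), "snapshots (kcal/mol):\n")
  for (k in names(x$mean))
    cat(sprintf("  %-8s %8.2f +/- %.2f\n", k, x$mean[k], x$sd[k]))
  cat(sprintf("  -TdS     %8s\n",
              ifelse(is.na(x$components$minus_T_dS), "<none>",
                     sprintf("%.2f", x$components$minus_T_dS))))
  cat(sprintf("  dG_bind  %8.2f%s\n", x$dG,
              if (isFALSE(x$entropy_included)) "  (enthalpy only)" else ""))
  invisible(x)
}

#' SIE per-snapshot pipeline
#'
#' For each selected frame: intermolecular Coulomb at the interior
#' dielectric D_in, van der Waals interaction, the reaction-field change
#' from the generalized-Born surrogate at D_in, and the scaled-radius
#' (rho) surface term `gamma * dMSA`; the per-frame SIE score and its mean
#' and snapshot dispersion are reported.
#'
#' @param traj a complex [trajectory()].
#' @param top a [topology()].
#' @param frame_sel optional [frame_selection()].
#' @param params a [sie_params()].
#' @param surface a [surface_params()] for the molecular-surface term;
#'   defaults to a zero-probe surface with `radius_scale = params$rho`.
#' @param gb a [gb_params()] for the reaction-field surrogate; defaults to
#'   `gb_params(interior_dielectric = params$interior_dielectric)`.
#' @return A list of class `sie_result`: `per_frame` (`time`,
#'   `coulomb_Din`, `vdw`, `reaction_field`, `msa_term`, `dG`), `mean`,
#'   `sd`, `components` (mean [sie_components()]), `dG`.
#' @export
sie_pipeline <- function(traj, top, frame_sel = NULL, params = sie_params(),
                         surface = NULL, gb = NULL) {
  if (!is.null(frame_sel)) traj <- select_frames(traj, frame_sel)
  surface <- surface %||%
    surface_params(probe_radius = 0, radius_scale = params$rho)
  gb <- gb %||% gb_params(interior_dielectric = params$interior_dielectric)
  nf <- n_frames(traj)
  ec <- vdw <- rf <- msa <- numeric(nf)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    ec[f] <- coulomb_energy(co, top, dielectric = params$interior_dielectric)
    vdw[f] <- lj_energy(co, top)
    rf[f] <- delta_gpol_binding(co, top, gb)
    msa[f] <- params$gamma_msa * delta_msa(co, top, surface)
  }
  dg <- vapply(seq_len(nf), function(f)
    sie_score(sie_components(ec[f], vdw[f], rf[f], msa[f]), params),
    numeric(1))
  per_frame <- data.frame(time = traj$times, coulomb_Din = ec, vdw = vdw,
                          reaction_field = rf, msa_term = msa, dG = dg)
  mn <- c(coulomb_Din = mean(ec), vdw = mean(vdw), reaction_field = mean(rf),
          msa_term = mean(msa), dG = mean(dg))
  sdv <- c(coulomb_Din = snapshot_sd(ec), vdw = snapshot_sd(vdw),
           reaction_field = snapshot_sd(rf), msa_term = snapshot_sd(msa),
           dG = snapshot_sd(dg))
  structure(list(per_frame = per_frame, mean = mn, sd = sdv,
                 components = sie_components(mn["coulomb_Din"], mn["vdw"],
                                             mn["reaction_field"],
                                             mn["msa_term"]),
                 dG = mn[["dG"]], params = params),
            class = "sie_result")
}

#' @export
print.sie_result <- function(x, ...) {
  cat("SIE over", nrow(x$per_frame), "snapshots (kcal/mol):\n")
  for (k in names(x$mean))
    cat(sprintf("  %-14s %8.2f +/- %.2f\n", k, x$mean[k], x$sd[k]))
  invisible(x)
}

#' Per-residue decomposition of the inhibitor-protein interaction
#'
#' For every receptor residue, the frame-averaged sum of its atoms' pairwise
#' electrostatic (dielectric 1) and van der Waals interactions with all
#' ligand atoms, plus a half-share of the generalized-Born cross-terms
#' between that residue's atoms and the ligand (the usual 50/50 attribution
#' of a pair term to the two residues involved). The ele+vdw entries
#' partition the total interaction energy exactly.
#'
#' @param traj a complex [trajectory()].
#' @param top a [topology()].
#' @param frame_sel optional [frame_selection()].
#' @param gb a [gb_params()].
#' @return A data frame of class `residue_decomposition` with columns
#'   `residue_index`, `residue_name`, `ele`, `vdw`, `gb`, `total`
#'   (kcal/mol), one row per receptor residue.
#' @export
residue_decomposition <- function(traj, top, frame_sel = NULL,
                                  gb = gb_params()) {
  if (!is.null(frame_sel)) traj <- select_frames(traj, frame_sel)
  rec <- top$receptor; lig <- top$ligand
  res_of <- top$atoms$residue_index[rec]
  resids <- sort(unique(res_of))
  grp <- factor(res_of, levels = resids)
  nf <- n_frames(traj)
  acc <- matrix(0, length(resids), 3,
                dimnames = list(NULL, c("ele", "vdw", "gb")))
  cplx <- c(rec, lig)
  i_rec <- match(rec, cplx); i_lig <- match(lig, cplx)
  for (f in seq_len(nf)) {
    co <- frame_coords(traj, f)
    e_mat <- .coulomb_pair_matrix(co, top, rec, lig, dielectric = 1)
    v_mat <- .lj_pair_matrix(co, top, rec, lig)
    radii <- effective_born_radii(co, top, cplx, gb)
    gmat <- .gb_energy_matrix(co[cplx, , drop = FALSE],
                              top$atoms$charge[cplx], radii, gb)
    # receptor-ligand cross energy for atom i: sum_j (E_ij + E_ji)/2 = row sum
    gb_atom <- rowSums(gmat[i_rec, i_lig, drop = FALSE])
    acc[, "ele"] <- acc[, "ele"] + rowsum(rowSums(e_mat), grp)[, 1]
    acc[, "vdw"] <- acc[, "vdw"] + rowsum(rowSums(v_mat), grp)[, 1]
    acc[, "gb"] <- acc[, "gb"] + rowsum(gb_atom, grp)[, 1]
  }
  acc <- acc / nf
  name_of <- top$atoms$residue_name[rec][match(resids, res_of)]
  out <- data.frame(residue_index = resids, residue_name = name_of,
                    ele = acc[, "ele"], vdw = acc[, "vdw"], gb = acc[, "gb"],
                    total = rowSums(acc))
  rownames(out) <- NULL
  class(out) <- c("residue_decomposition", "data.frame")
  out
}
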