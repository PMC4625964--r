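# Superposition-based trajectory analysis: Kabsch fitting, RMSD/RMSF,
# the normalized dynamic cross-correlation matrix, and PCA of the
# coordinate covariance. All fits are mass-unweighted.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' selected atoms of `mobile` onto `reference` (SVD solution; reflections
#' excluded by sign correction of the smallest singular direction).
#'
#' @param mobile,reference N x 3 coordinate matrices (Angstrom).
#' @param selection atom indices used for the fit (default: all). At least 3
#'   non-collinear atoms are required.
#' @return A list of class `superposition` with elements `rotation` (3 x 3,
#'   determinant +1), `translation` (length-3, Angstrom) and `rmsd`
#'   (Angstrom over the selection). The fitted coordinates of atom x are
#'   `x %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3) stop("need at least 3 atoms to superpose")
  A <- mobile[selection, , drop = FALSE]
  B <- reference[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity: rank of centered reference < 2
  sv_chk <- svd(B0)$d
  if (sv_chk[2] < 1e-8 * max(sv_chk[1], 1))
    stop("degenerate (collinear) selection: superposition is ill-defined")
  H <- crossprod(A0, B0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  translation <- cb - as.numeric(ca %*% R)
  fitted <- sweep(A %*% R, 2, translation, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = translation, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition transform to full coordinates
#' @param coords N x 3 matrix.
#' @param fit a `superposition` from [kabsch_superpose()].
#' @return transformed N x 3 matrix.
#' @export
apply_superposition <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2, fit$translation, `+`)
}

#' Coordinate RMSD between two frames over a selection (no fitting)
#' @keywords internal
#' @noRd
.raw_rmsd <- function(a, b, selection) {
  sqrt(mean(rowSums((a[selection, , drop = FALSE] -
                       b[selection, , drop = FALSE])^2)))
}

#' Per-frame RMSD series relative to a reference structure
#'
#' Each frame is superposed onto `reference` using `fit_selection`, then the
#' RMSD is measured over `measure_selection` (defaults to the fit selection).
#' The conventional use fits and measures on the backbone (N, CA, C, O).
#'
#' @param traj a [trajectory()].
#' @param reference N x 3 reference coordinates (e.g. the initial minimized
#'   structure).
#' @param fit_selection,measure_selection atom index vectors.
#' @return A list of class `rmsd_series`: `rmsd` (per-frame, Angstrom),
#'   `times` (ps), `mean`, and `range` (max - min).
#' @export
rmsd_series <- function(traj, reference, fit_selection = NULL,
                        measure_selection = NULL) {
  n <- traj$n_atoms
  fit_selection <- fit_selection %||% seq_len(n)
  measure_selection <- measure_selection %||% fit_selection
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    co <- frame_coords(traj, f)
    fit <- kabsch_superpose(co, reference, fit_selection)
    .raw_rmsd(apply_superposition(co, fit), reference, measure_selection)
  }, numeric(1))
  structure(list(rmsd = vals, times = traj$times, mean = mean(vals),
                 range = diff(range(vals))),
            class = "rmsd_series")
}

# Fit every frame to a common reference, iterating fit-to-mean once:
# fit all frames to the first frame, form the mean structure, refit to it.
#' @keywords internal
#' @noRd
.fit_frames_to_mean <- function(traj, selection) {
  nf <- n_frames(traj)
  frames <- lapply(seq_len(nf), function(f) frame_coords(traj, f))
  ref <- frames[[1]]
  fit1 <- lapply(frames, function(co)
    apply_superposition(co, kabsch_superpose(co, ref, selection)))
  mean_xyz <- Reduce(`+`, fit1) / nf
  lapply(fit1, function(co)
    apply_superposition(co, kabsch_superpose(co, mean_xyz, selection)))
}

# frames fitted to their mean, or raw when fit = FALSE or the selection is
# too small to define a superposition (< 3 atoms)
#' @keywords internal
#' @noRd
.fitted_or_raw <- function(traj, selection, fit) {
  if (fit && length(selection) >= 3) .fit_frames_to_mean(traj, selection)
  else lapply(seq_len(n_frames(traj)), function(f) frame_coords(traj, f))
}

#' Per-atom RMSF profile
#'
#' Root-mean-square fluctuation of each selected atom about its time-mean
#' position, after superposing all frames onto their mean structure (the fit
#' is performed internally; fit-to-mean iterated once). Typically applied to
#' the C-alpha selection, giving a per-residue flexibility profile.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param selection atom indices (default: all atoms).
#' @param fit superpose frames onto their mean structure first (default
#'   TRUE). Set FALSE for frames already expressed in a common reference
#'   frame (e.g. synthetic Gaussian displacements about a fixed structure),
#'   where the fit would absorb designed collective motion.
#' @return A data frame of class `rmsf_profile` with columns `atom`,
#'   `residue_index`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj, selection = NULL, fit = TRUE) {
  if (n_frames(traj) < 2)
    stop("RMSF is undefined for a single-frame trajectory")
  selection <- selection %||% seq_len(traj$n_atoms)
  fitted <- .fitted_or_raw(traj, selection, fit)
  sel_frames <- lapply(fitted, function(co) co[selection, , drop = FALSE])
  mean_xyz <- Reduce(`+`, sel_frames) / length(sel_frames)
  msd <- Reduce(`+`, lapply(sel_frames, function(co)
    rowSums((co - mean_xyz)^2))) / length(sel_frames)
  res <- if (!is.null(traj$topology))
    traj$topology$atoms$residue_index[selection] else selection
  out <- data.frame(atom = selection, residue_index = res, rmsf = sqrt(msd))
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Dynamic cross-correlation matrix
#'
#' Normalized cross-correlation of atomic positional fluctuations:
#' `c_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)`, where `dr_i` is the
#' displacement of atom i from its trajectory-mean position and the average
#' runs over frames (fitted internally to the mean structure). Entries lie in
#' `[-1, 1]`: positive values mark correlated motion, negative values
#' anti-correlated motion. Zero-variance atoms get off-diagonal 0 (with a
#' warning) rather than NaN.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param selection atom indices (default: all; conventionally C-alpha).
#' @inheritParams rmsf_profile
#' @return A matrix of class `dccm_matrix` (symmetric, unit diagonal) with
#'   residue identifiers as dimnames when a topology is attached.
#' @export
dccm <- function(traj, selection = NULL, fit = TRUE) {
  if (n_frames(traj) < 2) stop("DCCM requires at least 2 frames")
  selection <- selection %||% seq_len(traj$n_atoms)
  fitted <- .fitted_or_raw(traj, selection, fit)
  sel_frames <- lapply(fitted, function(co) co[selection, , drop = FALSE])
  nf <- length(sel_frames); nsel <- length(selection)
  mean_xyz <- Reduce(`+`, sel_frames) / nf
  # displacement matrix per axis: nf x nsel
  dx <- t(vapply(sel_frames, function(co) co[, 1] - mean_xyz[, 1], numeric(nsel)))
  dy <- t(vapply(sel_frames, function(co) co[, 2] - mean_xyz[, 2], numeric(nsel)))
  dz <- t(vapply(sel_frames, function(co) co[, 3] - mean_xyz[, 3], numeric(nsel)))
  cov_ij <- (crossprod(dx) + crossprod(dy) + crossprod(dz)) / nf
  v <- diag(cov_ij)
  zero <- v <= .Machine$double.eps * max(v, 1)
  if (any(zero))
    warning(sum(zero), " zero-variance atom(s): correlations set to 0")
  denom <- sqrt(pmax(v, .Machine$double.xmin))
  cc <- cov_ij / tcrossprod(denom)
  cc[zero, ] <- 0; cc[, zero] <- 0
  diag(cc) <- 1
  cc <- (cc + t(cc)) / 2
  cc[cc > 1] <- 1; cc[cc < -1] <- -1
  if (!is.null(traj$topology)) {
    lab <- with(traj$topology$atoms[selection, ],
                paste0(residue_name, residue_index))
    dimnames(cc) <- list(lab, lab)
  }
  class(cc) <- c("dccm_matrix", "matrix", "array")
  cc
}

#' Principal component analysis of the coordinate covariance
#'
#' Diagonalizes the 3N x 3N covariance matrix of the fitted coordinates of
#' the selected atoms. The leading eigenvalues capture the concerted,
#' large-amplitude motions; the cumulative fraction of the first k reports
#' how much of the total mean-square fluctuation they carry.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param selection atom indices (default: all; conventionally C-alpha).
#' @param k number of leading components to summarize (default 6).
#' @inheritParams rmsf_profile
#' @return A list of class `pca_spectrum`: `eigenvalues` (descending, A^2),
#'   `cumulative_fraction`, `first_k_fraction` (percent), `k`, `trace`.
#' @export
covariance_pca <- function(traj, selection = NULL, k = 6, fit = TRUE) {
  if (n_frames(traj) < 2) stop("PCA requires at least 2 frames")
  selection <- selection %||% seq_len(traj$n_atoms)
  if (k > 3 * length(selection))
    stop("k exceeds the 3N degrees of freedom of the selection")
  fitted <- .fitted_or_raw(traj, selection, fit)
  X <- do.call(rbind, lapply(fitted, function(co)
    as.numeric(t(co[selection, , drop = FALSE]))))
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / nrow(Xc)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  tot <- sum(ev)
  cum <- if (tot > 0) cumsum(ev) / tot else rep(0, length(ev))
  structure(list(eigenvalues = ev, cumulative_fraction = cum,
                 first_k_fraction = 100 * (if (tot > 0) cum[k] else 0),
                 k = k, trace = tot),
            class = "pca_spectrum")
}

#' @export
print.pca_spectrum <- function(x, ...) {
  cat(sprintf("covariance PCA: trace %.4g A^2; first %d components %.1f%%\n",
              x$trace, x$k, x$first_k_fraction))
  invisible(x)
}

#' Select atom indices by atom name
#'
#' Convenience selector: `calpha_selection()` returns the C-alpha atoms,
#' `backbone_selection()` the protein backbone (N, CA, C, O).
#'
#' @param top a [topology()].
#' @param subset optional atom index pool to intersect with.
#' @return integer atom indices.
#' @export
calpha_selection <- function(top, subset = NULL) {
  idx <- which(top$atoms$name == "CA")
  if (!is.null(subset)) idx <- intersect(idx, subset)
  idx
}

#' @rdname calpha_selection
#' @export
backbone_selection <- function(top, subset = NULL) {
  idx <- which(top$atoms$name %in% c("N", "CA", "C", "O"))
  if (!is.null(subset)) idx <- intersect(idx, subset)
  idx
}
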