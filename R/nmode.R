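# Normal-mode vibrational entropy for toy systems: the analysis energy
# function is intra-selection Coulomb + Lennard-Jones (1-2 bonded pairs
# excluded) plus harmonic bonds E = k/2 (r - r0)^2 supplied by the topology,
# so the sidecar's k is the literal spring constant. The structure is driven
# to a local minimum, a mass-weighted numerical Hessian (central differences
# of the analytic gradient) is diagonalized with the rigid-body modes
# projected out, and the harmonic-oscillator vibrational entropy is summed
# over the remaining frequencies.

# energy and analytic gradient of the intra-selection toy force field;
# x is the flattened (x1,y1,z1,...) coordinate vector of the selection.
#' @keywords internal
#' @noRd
.intra_energy_grad <- function(x, top, selection) {
  n <- length(selection)
  co <- matrix(x, ncol = 3, byrow = TRUE)
  q <- top$atoms$charge[selection]
  sig <- top$atoms$lj_sigma[selection]
  eps <- top$atoms$lj_epsilon[selection]
  bonds <- top$bonds
  bonded <- matrix(FALSE, n, n)
  bl <- NULL
  if (!is.null(bonds)) {
    keep <- bonds$i %in% selection & bonds$j %in% selection
    bl <- bonds[keep, , drop = FALSE]
    if (nrow(bl)) {
      bi <- match(bl$i, selection); bj <- match(bl$j, selection)
      bonded[cbind(bi, bj)] <- TRUE; bonded[cbind(bj, bi)] <- TRUE
      bl$ii <- bi; bl$jj <- bj
    }
  }
  E <- 0
  G <- matrix(0, n, 3)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dvec <- co[i, ] - co[j, ]
    r <- sqrt(sum(dvec^2))
    if (bonded[i, j]) next
    # Coulomb
    ec <- .const$k_e * q[i] * q[j] / r
    gc_ <- -ec / r^2 * dvec
    # LJ
    s <- (sig[i] + sig[j]) / 2
    e <- sqrt(eps[i] * eps[j])
    sr6 <- (s / r)^6
    ev <- 4 * e * (sr6^2 - sr6)
    dvdr <- 4 * e * (-12 * sr6^2 + 6 * sr6) / r
    gv <- dvdr * dvec / r
    E <- E + ec + ev
    G[i, ] <- G[i, ] + gc_ + gv
    G[j, ] <- G[j, ] - gc_ - gv
  }
  if (!is.null(bl) && nrow(bl)) for (b in seq_len(nrow(bl))) {
    i <- bl$ii[b]; j <- bl$jj[b]
    dvec <- co[i, ] - co[j, ]
    r <- sqrt(sum(dvec^2))
    E <- E + 0.5 * bl$k[b] * (r - bl$r0[b])^2
    gb <- bl$k[b] * (r - bl$r0[b]) * dvec / r
    G[i, ] <- G[i, ] + gb
    G[j, ] <- G[j, ] - gb
  }
  list(energy = E, gradient = as.numeric(t(G)))
}

#' @keywords internal
#' @noRd
.minimize_structure <- function(x0, top, selection, gtol = 1e-8,
                                max_rounds = 8) {
  fn <- function(x) .intra_energy_grad(x, top, selection)$energy
  gr <- function(x) .intra_energy_grad(x, top, selection)$gradient
  x <- x0
  for (round in seq_len(max_rounds)) {
    opt <- stats::optim(x, fn, gr, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-16))
    x <- opt$par
    if (sqrt(sum(gr(x)^2)) <= gtol) break
  }
  gnorm <- sqrt(sum(gr(x)^2))
  list(coords = matrix(x, ncol = 3, byrow = TRUE), gradient_norm = gnorm)
}

# numerical Hessian by central differences of the analytic gradient
#' @keywords internal
#' @noRd
.numerical_hessian <- function(x, top, selection, h = 1e-4) {
  m <- length(x)
  H <- matrix(0, m, m)
  for (k in seq_len(m)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    H[, k] <- (.intra_energy_grad(xp, top, selection)$gradient -
                 .intra_energy_grad(xm, top, selection)$gradient) / (2 * h)
  }
  H
}

# orthonormal basis of mass-weighted rigid-body modes (<= 6 vectors;
# 5 for linear molecules, where rotation about the axis degenerates)
#' @keywords internal
#' @noRd
.rigid_mode_basis <- function(coords, masses) {
  n <- nrow(coords)
  sm <- sqrt(masses)
  com <- colSums(coords * masses) / sum(masses)
  rel <- sweep(coords, 2, com)
  vecs <- list()
  for (ax in 1:3) {                      # translations
    v <- matrix(0, n, 3); v[, ax] <- sm
    vecs[[length(vecs) + 1]] <- as.numeric(t(v))
  }
  axes <- diag(3)
  for (ax in 1:3) {                      # rotations
    cr <- t(apply(rel, 1, function(p) c(
      axes[ax, 2] * p[3] - axes[ax, 3] * p[2],
      axes[ax, 3] * p[1] - axes[ax, 1] * p[3],
      axes[ax, 1] * p[2] - axes[ax, 2] * p[1])))
    v <- cr * sm
    vecs[[length(vecs) + 1]] <- as.numeric(t(v))
  }
  V <- do.call(cbind, vecs)
  # SVD-based orthonormalization: robust to the degenerate rotation of a
  # linear molecule (a near-zero column)
  sv <- svd(V)
  keep <- sv$d > 1e-8 * max(sv$d)
  sv$u[, keep, drop = FALSE]
}

#' Harmonic-oscillator vibrational entropy
#'
#' `S = R * sum_k [ x_k/(e^{x_k}-1) - ln(1 - e^{-x_k}) ]` with
#' `x_k = h nu_k / (k_B T)`.
#'
#' @param frequencies vibrational frequencies in Hz.
#' @param temperature temperature in K.
#' @return entropy in kcal mol^-1 K^-1.
#' @export
ho_vibrational_entropy <- function(frequencies, temperature) {
  if (temperature <= 0) return(0)
  x <- 2 * pi * frequencies * .const$hbar_over_kB / temperature
  .const$R_gas * sum(x / expm1(x) - log1p(-exp(-x)))
}

#' Normal-mode vibrational entropy of one state
#'
#' Minimizes the intra-selection toy energy (harmonic bonds + non-bonded
#' Coulomb/LJ), builds the mass-weighted numerical Hessian (central
#' differences, step `h`), projects out the rigid-body translations and
#' rotations, and converts the remaining eigenvalues to harmonic-oscillator
#' frequencies and vibrational entropy at `temperature`. Imaginary
#' frequencies beyond the rigid modes abort with an error reporting their
#' count (the structure is not at a minimum).
#'
#' @param coords N x 3 coordinate matrix of the full system (Angstrom).
#' @param top a [topology()].
#' @param selection atom indices of the state (e.g. receptor, ligand, or
#'   both for the complex).
#' @param temperature temperature in K (default 300).
#' @param minimize drive the structure to a local minimum first
#'   (default TRUE).
#' @param gtol gradient-norm convergence tolerance, kcal mol^-1 A^-1.
#' @param h Hessian finite-difference step, Angstrom.
#' @return A list of class `nmode_result`: `frequencies` (Hz, ascending),
#'   `entropy` (kcal mol^-1 K^-1), `minus_TS` (kcal/mol), `n_rigid`,
#'   `gradient_norm`, `coords` (minimized selection coordinates).
#' @export
normal_mode_entropy <- function(coords, top, selection = NULL,
                                temperature = 300, minimize = TRUE,
                                gtol = 1e-8, h = 1e-4) {
  selection <- selection %||% seq_len(top$n_atoms)
  x0 <- as.numeric(t(coords[selection, , drop = FALSE]))
  if (minimize) {
    mz <- .minimize_structure(x0, top, selection, gtol = gtol)
    x <- as.numeric(t(mz$coords)); gnorm <- mz$gradient_norm
  } else {
    x <- x0
    gnorm <- sqrt(sum(.intra_energy_grad(x, top, selection)$gradient^2))
  }
  H <- .numerical_hessian(x, top, selection, h = h)
  H <- (H + t(H)) / 2
  masses <- top$atoms$mass[selection]
  invsm <- 1 / sqrt(rep(masses, each = 3))
  Hmw <- H * tcrossprod(invsm)
  co <- matrix(x, ncol = 3, byrow = TRUE)
  Q <- .rigid_mode_basis(co, masses)
  P <- diag(nrow(Hmw)) - tcrossprod(Q)
  Hp <- P %*% Hmw %*% P
  Hp <- (Hp + t(Hp)) / 2
  ev <- eigen(Hp, symmetric = TRUE, only.values = TRUE)$values
  scale_tol <- 1e-6 * max(abs(ev), 1e-12)
  n_rigid <- ncol(Q)
  # drop the n_rigid eigenvalues closest to zero (the projected modes)
  ord <- order(abs(ev))
  vib <- ev[-ord[seq_len(n_rigid)]]
  n_imag <- sum(vib < -scale_tol)
  if (n_imag > 0)
    stop(n_imag, " imaginary frequenc(ies) beyond the rigid-body modes: ",
         "structure is not minimized")
  vib <- sort(pmax(vib, 0))
  freq <- sqrt(vib * .const$omega2_SI) / (2 * pi)
  S <- ho_vibrational_entropy(freq, temperature)
  structure(list(frequencies = freq, entropy = S,
                 minus_TS = -temperature * S, n_rigid = n_rigid,
                 gradient_norm = gnorm, coords = co),
            class = "nmode_result")
}

#' Normal-mode binding entropy penalty
#'
#' `-T dS = -T (S_complex - S_receptor - S_ligand)`, each state minimized
#' and analyzed independently from the same starting frame (single-trajectory
#' convention). Positive values penalize binding.
#'
#' @param coords N x 3 complex coordinates (Angstrom).
#' @param top a [topology()] with receptor/ligand selections.
#' @inheritParams normal_mode_entropy
#' @return A list: `minus_T_dS` (kcal/mol), and the three per-state
#'   [normal_mode_entropy()] results (`complex`, `receptor`, `ligand`).
#' @export
binding_entropy <- function(coords, top, temperature = 300, ...) {
  st_c <- normal_mode_entropy(coords, top, c(top$receptor, top$ligand),
                              temperature, ...)
  st_r <- normal_mode_entropy(coords, top, top$receptor, temperature, ...)
  st_l <- normal_mode_entropy(coords, top, top$ligand, temperature, ...)
  dS <- st_c$entropy - st_r$entropy - st_l$entropy
  list(minus_T_dS = -temperature * dS, complex = st_c, receptor = st_r,
       ligand = st_l)
}
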