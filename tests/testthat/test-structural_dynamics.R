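test_that("Kabsch superposition recovers rigid motions exactly", {
  co <- random_coords(8, seed = 3)
  fit <- kabsch_superpose(co, co)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  moved <- rigid_copy(co, theta = pi / 2, shift = c(4, 0, -7))
  fit2 <- kabsch_superpose(moved, co)
  expect_lt(fit2$rmsd, 1e-10)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-10)
  # collinear selections are rejected
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("Kabsch RMSD matches brute-force minimization over rotations", {
  # oracle: optimal translation is centroid alignment; minimize over Euler
  # angles by coarse grid + local refinement
  ref <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0), c(1, 1, 2))
  set.seed(9)
  mob <- rigid_copy(ref + matrix(rnorm(12, sd = 0.3), 4, 3), theta = 1.1)
  euler_rot <- function(a) {
    Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
    Rz(a[1]) %*% Ry(a[2]) %*% Rz(a[3])
  }
  A0 <- sweep(mob, 2, colMeans(mob))
  B0 <- sweep(ref, 2, colMeans(ref))
  obj <- function(a) sqrt(mean(rowSums((A0 %*% euler_rot(a) - B0)^2)))
  grid <- as.matrix(expand.grid(a1 = seq(0, 2 * pi, length.out = 13),
                                a2 = seq(0, pi, length.out = 7),
                                a3 = seq(0, 2 * pi, length.out = 13)))
  vals <- apply(grid, 1, obj)
  best <- optim(grid[which.min(vals), ], obj,
                control = list(reltol = 1e-15, maxit = 5000))$value
  fit <- kabsch_superpose(mob, ref)
  expect_equal(fit$rmsd, best, tolerance = 1e-6)
  expect_lte(fit$rmsd, best + 1e-9)
})

test_that("RMSD series is zero for rigid motions and matches hand arithmetic", {
  co <- random_coords(6, seed = 5)
  frames <- list(co, rigid_copy(co), rigid_copy(co, theta = 2, shift = c(0, 9, 1)))
  traj <- trajectory_from_frames(frames)
  rs <- rmsd_series(traj, co)
  expect_lt(max(rs$rmsd), 1e-10)
  # one atom displaced by 1 A with the other three pinned: RMSD = 0.5 A
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(1, 1, 1))
  moved <- ref
  moved[4, ] <- moved[4, ] + c(0, 0, 1)
  traj2 <- trajectory_from_frames(list(ref, moved))
  rs2 <- rmsd_series(traj2, ref, fit_selection = 1:3,
                     measure_selection = 1:4)
  expect_equal(rs2$rmsd[2], 0.5, tolerance = 1e-10)
  # superposition never increases RMSD
  set.seed(21)
  for (i in 1:5) {
    a <- random_coords(10, seed = 30 + i)
    b <- a + matrix(rnorm(30, sd = 0.5), 10, 3)
    raw <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(kabsch_superpose(a, b)$rmsd, raw + 1e-12)
  }
})

test_that("RMSF recovers designed fluctuations", {
  co <- random_coords(5, seed = 7)
  expect_error(rmsf_profile(trajectory_from_frames(list(co))), "single-frame")
  # identical frames: zero profile
  traj0 <- trajectory_from_frames(list(co, co, co))
  expect_equal(max(rmsf_profile(traj0)$rmsf), 0, tolerance = 1e-12)
  # one atom oscillating +/- d along x, equal occupancy: RMSF = d
  d <- 0.4
  up <- co; up[3, 1] <- up[3, 1] + d
  dn <- co; dn[3, 1] <- dn[3, 1] - d
  trajd <- trajectory_from_frames(list(up, dn))
  prof <- rmsf_profile(trajd, fit = FALSE)
  expect_equal(prof$rmsf[3], d, tolerance = 1e-12)
  expect_equal(max(prof$rmsf[-3]), 0, tolerance = 1e-12)
  # Gaussian displacements with per-axis variance s2: RMSF -> s*sqrt(3)
  s2 <- 0.09
  spec <- correlated_motion_spec(rep(1, 12), matrix(0, 1, 1),
                                 per_atom_variance = s2, n_frames = 2000,
                                 seed = 31)
  trajg <- sample_correlated_trajectory(random_coords(12, seed = 8), spec)
  profg <- rmsf_profile(trajg, fit = FALSE)
  expect_equal(mean(profg$rmsf), sqrt(3 * s2), tolerance = 0.05)
})

test_that("DCCM satisfies its invariants and flags zero-variance atoms", {
  for (seed in 1:4) {
    spec <- correlated_motion_spec(rep(1:2, each = 5),
                                   matrix(c(0.6, -0.3, -0.3, 0.6), 2, 2),
                                   per_atom_variance = 0.05, n_frames = 60,
                                   seed = seed)
    traj <- sample_correlated_trajectory(random_coords(10, seed = seed), spec)
    cc <- dccm(traj)
    expect_equal(unclass(cc), t(unclass(cc)), ignore_attr = TRUE)
    expect_equal(unname(diag(cc)), rep(1, 10))
    expect_true(all(cc >= -1 & cc <= 1))
  }
  # frozen atom: off-diagonal zeroed with a warning
  co <- random_coords(4, seed = 2)
  set.seed(4)
  frames <- lapply(1:20, function(i) {
    f <- co + matrix(rnorm(12, sd = 0.1), 4, 3)
    f[2, ] <- co[2, ]
    f
  })
  traj <- trajectory_from_frames(frames)
  expect_warning(cc <- dccm(traj, fit = FALSE), "zero-variance")
  expect_equal(unname(cc[2, -2]), rep(0, 3))
  expect_equal(unname(cc[2, 2]), 1)
})

test_that("DCCM recovers designed correlations: perfect anti-correlation and 0.8 blocks", {
  # mirrored displacements give c = -1 exactly
  base <- rbind(c(0, 0, 0), c(5, 0, 0))
  set.seed(13)
  frames <- lapply(1:50, function(i) {
    d <- rnorm(3, sd = 0.3)
    rbind(base[1, ] + d, base[2, ] - d)
  })
  cc <- dccm(trajectory_from_frames(frames), fit = FALSE)
  expect_equal(unname(cc[1, 2]), -1, tolerance = 1e-10)
  # two-block design with inter-block 0.8 recovered within 0.05
  spec <- correlated_motion_spec(rep(1:2, each = 10),
                                 matrix(c(0.9, 0.8, 0.8, 0.9), 2, 2),
                                 per_atom_variance = 0.09, n_frames = 5000,
                                 seed = 7)
  traj <- sample_correlated_trajectory(random_coords(20, seed = 42, sd = 4),
                                       spec)
  cc2 <- dccm(traj, fit = FALSE)
  expect_lt(abs(mean(cc2[1:10, 11:20]) - 0.8), 0.05)
})

test_that("DCCM and PCA are invariant under global rigid motion of all frames", {
  spec <- correlated_motion_spec(rep(1:2, each = 4),
                                 matrix(c(0.7, 0.2, 0.2, 0.7), 2, 2),
                                 per_atom_variance = 0.04, n_frames = 40,
                                 seed = 17)
  traj <- sample_correlated_trajectory(random_coords(8, seed = 6), spec)
  moved <- trajectory_from_frames(lapply(seq_len(n_frames(traj)), function(f)
    rigid_copy(frame_coords(traj, f), theta = 0.8, shift = c(5, -3, 2))),
    times = traj$times)
  expect_equal(unclass(dccm(traj)), unclass(dccm(moved)),
               tolerance = 1e-8, ignore_attr = TRUE)
  p1 <- covariance_pca(traj, k = 3)
  p2 <- covariance_pca(moved, k = 3)
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-8)
})

test_that("PCA spectrum conserves the trace and recovers designed structure", {
  # rigid trajectory: all eigenvalues vanish
  co <- random_coords(6, seed = 1)
  rigid <- trajectory_from_frames(list(co, rigid_copy(co),
                                       rigid_copy(co, theta = 0.4)))
  expect_lt(max(covariance_pca(rigid, k = 2)$eigenvalues), 1e-18)
  # isotropic independent noise: eigenvalues cluster at the variance
  s2 <- 0.04
  spec <- correlated_motion_spec(rep(1, 20), matrix(0, 1, 1),
                                 per_atom_variance = s2, n_frames = 5000,
                                 seed = 23)
  traj <- sample_correlated_trajectory(random_coords(20, seed = 3), spec)
  p <- covariance_pca(traj, k = 6, fit = FALSE)
  expect_equal(sum(p$eigenvalues), p$trace, tolerance = 1e-10)
  # sample-covariance eigenvalue spread for p = 60 dims at n = 5000 is
  # governed by Marchenko-Pastur: range ~ 4 sqrt(p/n) ~ 0.44 relative
  expect_lt((max(p$eigenvalues) - min(p$eigenvalues)) / s2,
            4.5 * sqrt(60 / 5000))
  expect_equal(mean(p$eigenvalues), s2, tolerance = 0.02)
  # one dominant collective mode of variance 10*s2 over background s2:
  # leading eigenvalue fraction ~ 11*s2 / (3N*s2 + 10*s2)
  n <- 10
  set.seed(33)
  v <- rnorm(3 * n); v <- v / sqrt(sum(v^2))
  ref <- random_coords(n, seed = 44)
  frames <- lapply(1:5000, function(i) {
    disp <- rnorm(3 * n, sd = sqrt(s2)) + v * rnorm(1, sd = sqrt(10 * s2))
    ref + matrix(disp, n, 3, byrow = TRUE)
  })
  trajd <- trajectory_from_frames(frames)
  pd <- covariance_pca(trajd, k = 1, fit = FALSE)
  frac_design <- (11 * s2) / (3 * n * s2 + 10 * s2)
  expect_equal(pd$first_k_fraction / 100, frac_design, tolerance = 0.05)
  expect_error(covariance_pca(trajd, k = 3 * n + 1), "3N")
})

test_that("RMSD and DCCM agree with bio3d on a shared case", {
  skip_if_not_installed("bio3d")
  set.seed(55)
  ref <- random_coords(10, seed = 5)
  frames <- lapply(1:15, function(i)
    rigid_copy(ref + matrix(rnorm(30, sd = 0.4), 10, 3), theta = 0.1 * i))
  traj <- trajectory_from_frames(frames)
  mine <- rmsd_series(traj, ref)$rmsd
  theirs <- bio3d::rmsd(as.numeric(t(ref)), traj$xyz, fit = TRUE)
  expect_equal(mine, as.numeric(theirs), tolerance = 5e-3)  # bio3d rounds
  # correlation on pre-fitted frames vs bio3d::dccm on the same matrix
  spec <- correlated_motion_spec(rep(1:2, each = 5),
                                 matrix(c(0.8, -0.4, -0.4, 0.8), 2, 2),
                                 per_atom_variance = 0.09, n_frames = 400,
                                 seed = 77)
  trajc <- sample_correlated_trajectory(ref, spec)
  mine_cc <- dccm(trajc, fit = FALSE)
  theirs_cc <- suppressWarnings(bio3d::dccm.xyz(trajc$xyz))
  expect_equal(unclass(mine_cc), unclass(theirs_cc), tolerance = 1e-6,
               ignore_attr = TRUE)
})
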