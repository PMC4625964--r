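test_that("MM-GBSA combination reproduces the packaged component rows", {
  t1 <- load_component_fixtures("mmgbsa")
  want <- c(PMI = -13.3, pDI = -10.7, WK23 = -8.4, WW8 = -8.9)
  for (cx in names(want)) {
    row <- t1[t1$complex == cx, ]
    got <- mmgbsa_combine(mmgbsa_components_from_row(row))
    expect_equal(as.numeric(got), want[[cx]], tolerance = 1e-10)
    expect_true(attr(got, "entropy_included"))
  }
  expect_equal(as.numeric(suppressWarnings(
    mmgbsa_combine(energy_components(0, 0, 0, 0)))), 0)
  expect_warning(g <- mmgbsa_combine(energy_components(-10, -5, 8, -1)),
                 "entropy")
  expect_false(attr(g, "entropy_included"))
  expect_equal(as.numeric(g), -8)
})

test_that("SIE score reproduces the packaged rows and is affine with slope alpha", {
  t2 <- load_component_fixtures("sie")
  want <- c(PMI = -10.71, pDI = -9.92, WK23 = -6.89, WW8 = -7.09)
  for (cx in names(want)) {
    row <- t2[t2$complex == cx, ]
    expect_equal(sie_score(sie_components_from_row(row)), want[[cx]],
                 tolerance = 0.011)
  }
  p <- sie_params()
  expect_equal(sie_score(sie_components(0, 0, 0, 0), p), p$constant_C)
  # affine in each component with slope alpha
  base <- sie_components(-20, -30, 25, -5)
  s0 <- sie_score(base, p)
  for (fld in names(base)) {
    pert <- base
    pert[[fld]] <- pert[[fld]] + 1
    expect_equal(sie_score(pert, p) - s0, p$alpha, tolerance = 1e-12)
  }
  # alpha = 0 collapses the score to the constant
  p0 <- sie_params(alpha = 0)
  expect_equal(sie_score(base, p0), p0$constant_C)
})

test_that("non-polar term follows gamma * area + beta", {
  expect_equal(nonpolar_energy(1000), 7.2, tolerance = 1e-12)
  expect_equal(nonpolar_energy(0), 0)
  # the buried-area change implied by a -9.5 kcal/mol non-polar term
  expect_equal(nonpolar_energy(-1319.4), -9.5, tolerance = 1e-3)
  expect_equal(nonpolar_energy(100, nonpolar_params(gamma = 0.05, beta = 2)),
               7, tolerance = 1e-12)
})

test_that("MM-GBSA pipeline components match closed-form oracles on a rigid toy", {
  # one receptor atom + one ligand atom, fixed geometry over 3 frames
  d <- 4.2; q <- c(0.8, -0.6); sig <- 3.1; eps <- 0.15
  a_rad <- c(1.6, 1.5)
  top <- simple_top(2, charge = q, sigma = sig, epsilon = eps,
                    gb_radius = a_rad, receptor = 1, ligand = 2)
  co <- rbind(c(0, 0, 0), c(d, 0, 0))
  traj <- trajectory_from_frames(list(co, co, co), topology = top)
  gb <- gb_params(); sp <- surface_params(radius_scale = 1)
  res <- mmgbsa_pipeline(traj, top, gb = gb, np = nonpolar_params(),
                         surface = sp)
  ke <- 332.0637
  expect_equal(res$mean[["ele"]], ke * q[1] * q[2] / d, tolerance = 1e-9)
  expect_equal(res$mean[["vdw"]], 4 * eps * ((sig / d)^12 - (sig / d)^6),
               tolerance = 1e-9)
  # gpol oracle: quadrature-based radii + explicit GB sums for each state
  red <- a_rad - gb$radius_offset
  scr <- top$atoms$gb_screen
  eff <- vapply(1:2, function(i) {
    j <- 3 - i
    I <- descreen_quad(d, red[i], scr[j] * red[j])
    psi <- I * red[i]
    1 / (1 / red[i] - tanh(gb$obc_alpha * psi - gb$obc_beta * psi^2 +
                             gb$obc_gamma * psi^3) / a_rad[i])
  }, numeric(1))
  pref <- -0.5 * ke * (1 / gb$interior_dielectric -
                         1 / gb$exterior_dielectric)
  fgb <- sqrt(d^2 + eff[1] * eff[2] * exp(-d^2 / (4 * eff[1] * eff[2])))
  g_cplx <- pref * (q[1]^2 / eff[1] + q[2]^2 / eff[2] +
                      2 * q[1] * q[2] / fgb)
  g_sep <- pref * (q[1]^2 / red[1] + q[2]^2 / red[2])
  expect_equal(res$mean[["gpol"]], g_cplx - g_sep, tolerance = 1e-6)
  # gnonpol oracle: two-sphere analytic buried area through the 0.0072 slope
  R1 <- a_rad[1] + 1.4; R2 <- a_rad[2] + 1.4
  dA <- two_sphere_area(R1, R2, d) - 4 * pi * (R1^2 + R2^2)
  expect_equal(res$mean[["gnonpol"]], 0.0072 * dA, tolerance = 0.01)
  # rigid geometry: zero dispersion; dG flagged enthalpy-only
  expect_equal(unname(res$sd), rep(0, 4))
  expect_false(res$entropy_included)
})

test_that("pipelines vanish in the separation limit and SIE tends to C", {
  tc <- make_toy_complex(toy_complex_spec(2, 2, 2, ligand_distance = 500))
  traj <- trajectory_from_frames(list(tc$frame, tc$frame),
                                 topology = tc$topology)
  res <- mmgbsa_pipeline(traj, tc$topology)
  expect_true(all(abs(res$mean) < 1e-3))
  sres <- sie_pipeline(traj, tc$topology,
                       surface = surface_params(probe_radius = 0,
                                                radius_scale = 1.1,
                                                n_sphere_points = 240))
  expect_true(all(abs(unlist(sres$components)) < 1e-3))
  expect_equal(sres$dG, -2.89, tolerance = 1e-3)
})

test_that("frame duplication keeps component means and rescales the N-1 dispersion", {
  tc <- make_toy_complex(toy_complex_spec(2, 2, 1))
  f2 <- tc$frame; f2[tc$topology$ligand, 1] <- f2[tc$topology$ligand, 1] + 0.5
  traj <- trajectory_from_frames(list(tc$frame, f2), topology = tc$topology)
  dup <- trajectory_from_frames(list(tc$frame, f2, tc$frame, f2),
                                topology = tc$topology)
  r1 <- mmgbsa_pipeline(traj, tc$topology)
  r2 <- mmgbsa_pipeline(dup, tc$topology)
  expect_equal(r2$mean, r1$mean, tolerance = 1e-12)
  # sample-SD dispersion: duplication scales by sqrt(2*(n-1)/(2n-1))
  expect_equal(unname(r2$sd), unname(r1$sd) * sqrt(2 * 1 / 3),
               tolerance = 1e-10)
})

test_that("residue decomposition partitions the interaction energy", {
  # single-residue receptor: decomposition total = full interaction energy
  top1 <- simple_top(3, charge = c(0.3, -0.2, -0.1),
                     residue_index = c(1, 1, 2), receptor = 1:2, ligand = 3)
  co <- rbind(c(0, 0, 0), c(2.8, 0.5, 0), c(1.2, 3.4, 0.2))
  traj <- trajectory_from_frames(list(co), topology = top1)
  d1 <- residue_decomposition(traj, top1)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$ele + d1$vdw,
               coulomb_energy(co, top1) + lj_energy(co, top1),
               tolerance = 1e-10)
  # a far, neutral second residue contributes nothing
  top2 <- simple_top(4, charge = c(0.3, -0.2, 0, -0.1), epsilon = c(0.1, 0.1, 0, 0.1),
                     residue_index = c(1, 1, 2, 3), receptor = 1:3, ligand = 4)
  co2 <- rbind(co[1:2, ], c(500, 500, 500), co[3, ])
  d2 <- residue_decomposition(trajectory_from_frames(list(co2),
                                                     topology = top2), top2)
  expect_lt(abs(d2$total[d2$residue_index == 2]), 1e-6)
  # random toy: conservation of ele+vdw over residues, multi-frame
  set.seed(8)
  n <- 8
  top3 <- simple_top(n, charge = runif(n, -0.5, 0.5),
                     residue_index = c(1, 1, 2, 2, 3, 3, 4, 4),
                     receptor = 1:6, ligand = 7:8)
  frames <- lapply(1:3, function(i) random_coords(n, sd = 4, seed = 60 + i))
  traj3 <- trajectory_from_frames(frames, topology = top3)
  d3 <- residue_decomposition(traj3, top3)
  tot <- mean(vapply(frames, function(f)
    coulomb_energy(f, top3) + lj_energy(f, top3), numeric(1)))
  expect_equal(sum(d3$ele + d3$vdw), tot, tolerance = 1e-8)
  # GB shares: receptor residues carry half the receptor-ligand cross-terms
  gbp <- gb_params()
  cross <- mean(vapply(frames, function(f) {
    radii <- effective_born_radii(f, top3, 1:n, gbp)
    E <- mdbind:::.gb_energy_matrix(f, top3$atoms$charge, radii, gbp)
    sum(E[1:6, 7:8]) + sum(E[7:8, 1:6])
  }, numeric(1)))
  expect_equal(sum(d3$gb), cross / 2, tolerance = 1e-8)
})
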