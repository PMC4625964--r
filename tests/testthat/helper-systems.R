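# Shared builders for small test systems.

# minimal topology from per-atom parameter vectors (defaults: inert carbons)
simple_top <- function(n, charge = 0, sigma = 3.4, epsilon = 0.1,
                       gb_radius = 1.7, gb_screen = 0.72, mass = 12.011,
                       receptor = integer(), ligand = integer(),
                       bonds = NULL, residue_index = NULL, name = NULL) {
  atoms <- data.frame(
    charge = rep_len(charge, n), lj_sigma = rep_len(sigma, n),
    lj_epsilon = rep_len(epsilon, n), gb_radius = rep_len(gb_radius, n),
    gb_screen = rep_len(gb_screen, n), mass = rep_len(mass, n))
  if (!is.null(residue_index)) atoms$residue_index <- residue_index
  if (!is.null(name)) atoms$name <- name
  topology(atoms, receptor = receptor, ligand = ligand, bonds = bonds)
}

# random compact coordinates, reproducibly
random_coords <- function(n, sd = 3, seed = 1) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = sd), n, 3)
}

# a rigid-motion copy of coordinates: rotation about z by theta + shift
rigid_copy <- function(coords, theta = pi / 3, shift = c(1, -2, 3)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  sweep(coords %*% R, 2, shift, `+`)
}

# analytic accessible area of two intersecting spheres with accessible
# radii R1, R2 at center distance d (each loses a spherical cap)
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# independent quadrature oracle for the pairwise descreening integral:
# (1/4pi) * int over the scaled sphere (radius s at distance d), excluding
# the ball of radius rho around the origin, of |x|^-4 dV
descreen_quad <- function(d, rho, s) {
  lo <- max(rho, d - s)
  hi <- d + s
  if (hi <= rho) return(0)
  f <- function(r) {
    mu <- (d^2 + r^2 - s^2) / (2 * d * r)
    mu <- pmin(1, pmax(-1, mu))
    (1 - mu) / r^2
  }
  0.5 * stats::integrate(f, lo, hi, rel.tol = 1e-12,
                         abs.tol = 1e-14)$value
}

# harmonic-oscillator entropy (kcal/mol/K) straight from the closed form
ho_entropy_oracle <- function(nu_hz, temp) {
  h <- 6.62607015e-34; kB <- 1.380649e-23
  Rk <- 1.98720425864083e-3
  x <- h * nu_hz / (kB * temp)
  Rk * sum(x / (exp(x) - 1) - log(1 - exp(-x)))
}
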