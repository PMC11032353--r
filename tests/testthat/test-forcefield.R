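# Scalar force-field terms: published constants, closed-form values,
# finite-difference derivative oracles and branch continuity.

scalar_deriv_check <- function(fn, xs, h = 1e-6, tol = 1e-6) {
  for (x in xs) {
    an <- fn(x)$deriv
    nu <- (fn(x + h)$energy - fn(x - h)$energy) / (2 * h)
    expect_equal(an, nu, tolerance = tol,
                 info = sprintf("derivative mismatch at x = %g", x))
  }
}

test_that("bond terms: model constants and quartic polynomial", {
  hp <- list(k = 2.39, b0 = 3.8)
  expect_equal(bond_energy(3.8, "harmonic", hp)$energy, 0)
  # 1 A extension at the default force constant
  expect_equal(bond_energy(4.8, "harmonic", hp)$energy, 2.39)
  set.seed(1)
  qp <- list(k2 = runif(1, 10, 100), k4 = runif(1, 100, 1000), b0 = 3.9)
  b <- runif(5, 3.0, 5.0)
  expect_equal(bond_energy(b, "quartic", qp)$energy,
               qp$k2 * (b - 3.9)^2 + qp$k4 * (b - 3.9)^4)
  scalar_deriv_check(function(x) bond_energy(x, "quartic", qp),
                     c(3.2, 3.9, 4.4))
  expect_error(bond_energy(3.8, "cubic", hp))
})

test_that("angle terms: peaks, flat flexible default, derivatives", {
  g13 <- list(eps = 1.3, r0 = 5.2, w = 0.6)
  expect_equal(angle_energy(5.2, "gaussian_13", g13)$energy, -1.3)
  expect_equal(angle_energy(1.1, "harmonic",
                            list(ka = 7, theta0 = 1.1))$energy, 0)
  scalar_deriv_check(function(x) angle_energy(x, "gaussian_13", g13),
                     c(4.0, 5.2, 6.5))
  # table proportional to sin(theta) gives constant energy, zero force
  grid <- seq(0.02 * pi, 0.98 * pi, length.out = 80)
  pr <- sin(grid); pr <- pr / (sum(pr) * diff(grid[1:2]))
  fx <- angle_energy(seq(0.3, 2.6, length.out = 9), "flexible",
                     list(table = list(grid = grid, prob = pr),
                          temperature_K = 300))
  expect_lt(diff(range(fx$energy)), 1e-4)
  expect_lt(max(abs(fx$deriv)), 2e-3)
  # flexible-table derivative matches the finite difference
  p2 <- gen_test_parameters(seed = 4)
  tab <- p2$flexible$angle[["A"]]
  scalar_deriv_check(function(x) angle_energy(x, "flexible",
    list(table = tab, temperature_K = 300)), c(0.8, 1.5, 2.3), tol = 1e-5)
  expect_warning(angle_energy(0.01, "flexible",
    list(table = tab, temperature_K = 300)), "clamped")
})

test_that("dihedral terms: periodic zeros, gaussian peak, derivatives", {
  pp <- list(k = 1.7, n = 1, phi0 = 0.4)
  expect_equal(dihedral_energy(0.4 + pi, "periodic", pp)$energy, 0,
               tolerance = 1e-12)
  gp <- list(eps = 2.1, phi0 = -0.9, sigma = 0.3)
  expect_equal(dihedral_energy(-0.9, "gaussian", gp)$energy, -2.1)
  # gaussian uses the minimum-image angular difference
  expect_equal(dihedral_energy(-0.9 + 2 * pi, "gaussian", gp)$energy, -2.1)
  set.seed(2)
  two <- list(k = runif(2), n = c(1, 3), phi0 = 0.2)
  phi <- runif(4, -pi, pi)
  expect_equal(dihedral_energy(phi, "periodic", two)$energy,
               two$k[1] * (1 + cos(phi - 0.2)) +
                 two$k[2] * (1 + cos(3 * (phi - 0.2))))
  scalar_deriv_check(function(x) dihedral_energy(x, "periodic", two),
                     c(-2, 0.3, 2.8))
  p2 <- gen_test_parameters(seed = 4)
  tabd <- p2$flexible$dihedral[["A"]]
  scalar_deriv_check(function(x) dihedral_energy(x, "flexible",
    list(table = tabd, temperature_K = 300)), c(-2.5, 0.1, 3.0), tol = 1e-5)
})

test_that("Go contacts: minimum at sigma, decay, direct value", {
  expect_equal(go_contact_energy(5, 5, 0.7)$energy, -0.7)
  expect_equal(go_contact_energy(5, 5, 0.7)$deriv, 0, tolerance = 1e-12)
  r <- seq(5, 40, length.out = 30)
  e <- go_contact_energy(r, 5, 1)$energy
  expect_true(all(diff(e) > 0) && all(e < 0))  # rises to 0 from below
  expect_equal(go_contact_energy(0.9 * 5, 5, 1)$energy,
               5 * (1 / 0.9)^12 - 6 * (1 / 0.9)^10)
  scalar_deriv_check(function(x) go_contact_energy(x, 5, 0.7),
                     c(4.2, 5, 7.5))
})

test_that("excluded volume: continuity at cutoffs and direct values", {
  ap <- list(eps = 0.6, sigma = 5)
  expect_equal(excluded_volume_energy(10, "aicg", ap)$energy, 0)
  expect_equal(excluded_volume_energy(5, "aicg", ap)$energy,
               0.6 * (1 - 2^-12))
  dp <- list(eps = 1, sigma = 5)
  expect_equal(excluded_volume_energy(5, "dna", dp)$energy, 0)
  for (style in c("aicg", "dna")) {
    par <- list(eps = 0.8, sigma = 5)
    rc <- if (style == "aicg") 10 else 5
    lo <- excluded_volume_energy(rc - 1e-8, style, par)$energy
    hi <- excluded_volume_energy(rc + 1e-8, style, par)$energy
    expect_lt(abs(lo - hi), 1e-10)
    scalar_deriv_check(function(x) excluded_volume_energy(x, style, par),
                       c(4, 4.6))
  }
})

test_that("HPS pair: well depth, switch continuity, hydropathy scaling", {
  rmin <- 2^(1 / 6) * 5
  expect_equal(hps_pair_energy(rmin, 5, 1, 0.2)$energy, -0.2)
  expect_equal(hps_pair_energy(30, 5, 0, 0.2)$energy, 0)
  set.seed(3)
  for (q in 1:5) {
    sig <- runif(1, 4, 7); lam <- runif(1, 0, 1.2)
    kn <- 2^(1 / 6) * sig
    d <- abs(hps_pair_energy(kn - 1e-9, sig, lam)$energy -
               hps_pair_energy(kn + 1e-9, sig, lam)$energy)
    expect_lt(d, 1e-10)
    scalar_deriv_check(function(x) hps_pair_energy(x, sig, lam),
                       c(0.9 * sig, 1.3 * sig, 2.5 * sig))
  }
})

test_that("solution permittivity matches the printed polynomials", {
  expect_equal(relative_permittivity(300, 0.15), 74.911, tolerance = 1e-5)
  # a(0) = 1: pure-temperature value
  eT <- 249.4 - 0.788 * 321 + 7.2e-4 * 321^2
  expect_equal(relative_permittivity(321, 0), eT)
  # independent product evaluation at another state point
  eT298 <- 249.4 - 0.788 * 298 + 7.2e-4 * 298^2
  aC01 <- 1 - 0.2551 * 0.1 + 5.151e-2 * 0.01 - 6.889e-3 * 0.001
  expect_equal(relative_permittivity(298, 0.1), eT298 * aC01)
  expect_error(relative_permittivity(150, 0.1), "range")
  expect_error(relative_permittivity(300, -0.1))
})

test_that("Debye length: closed form, scaling, monotonicity", {
  er <- 74.911
  # independent route via the Bjerrum length: 1/sqrt(4 pi l_B n)
  lB <- 332.0716 / (er * 0.0019872041 * 300)
  n_ion <- 2 * 0.15 * 6.02214076e23 * 1e-27  # ions per A^3
  expect_equal(debye_length(300, 0.15, er), 1 / sqrt(4 * pi * lB * n_ion),
               tolerance = 1e-4)
  expect_equal(debye_length(300, 0.6, er), debye_length(300, 0.15, er) / 2)
  lam <- debye_length(300, c(0.05, 0.1, 0.2, 0.5, 1), er)
  expect_true(all(diff(lam) < 0))
  expect_error(debye_length(300, 0, er), "ionic strength")
})

test_that("Debye-Hueckel pair term: limits and derivative", {
  expect_equal(debye_huckel_energy(7, 0, 1, 75, 8)$energy, 0)
  # infinite screening length recovers the bare Coulomb form
  expect_equal(debye_huckel_energy(7, 1, -1, 75, 1e12)$energy,
               -332.0716 / (75 * 7), tolerance = 1e-9)
  set.seed(4)
  for (q in 1:5) {
    r0 <- runif(1, 3, 20); lam <- runif(1, 4, 15)
    fn <- function(x) debye_huckel_energy(x, 1, 1, 74.911, lam)
    scalar_deriv_check(fn, r0)
  }
  expect_equal(debye_huckel_energy(40, 1, 1, 75, 8, r_cut = 35)$energy, 0)
})

test_that("Morse split: branch values and rep + attr identity", {
  mo <- morse_components(4.0, 3, 2, 4.0)
  expect_equal(mo$rep, 0)
  expect_equal(mo$attr, -3)
  expect_equal(morse_components(50, 3, 2, 4)$attr, 0, tolerance = 1e-6)
  set.seed(5)
  r <- runif(20, 2, 10)
  mo <- morse_components(r, 3, 2, 4)
  full <- 3 * (1 - exp(-2 * (r - 4)))^2 - 3
  expect_equal(mo$rep + mo$attr, full)
  expect_equal(mo$drep + mo$dattr,
               2 * 3 * 2 * exp(-2 * (r - 4)) * (1 - exp(-2 * (r - 4))))
})

test_that("angle modulation: plateau, knots, half-way value", {
  g <- 0.35
  expect_equal(angle_modulation(0, g)$f, 1)
  expect_equal(angle_modulation(2 * g, g)$f, 0)
  expect_equal(angle_modulation(1.5 * g, g)$f, 0.5)
  for (dt in c(g, 2 * g)) {
    lo <- angle_modulation(dt - 1e-9, g)$f
    hi <- angle_modulation(dt + 1e-9, g)$f
    expect_lt(abs(lo - hi), 1e-8)
  }
  expect_equal(angle_modulation(-1.5 * g, g)$f, 0.5)  # even function
  xs <- seq(-2.2 * g, 2.2 * g, length.out = 23)
  f <- angle_modulation(xs, g)$f
  expect_true(all(f >= 0 & f <= 1))
})
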