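## Scalar energy terms of the residue-level CG force field. Every function
## returns the energy together with its analytic derivative with respect to
## its scalar argument (distance or angle); Cartesian forces are assembled
## from these by the chain rule in energy.R. All functions are vectorized.

#' Bonded stretch energy
#'
#' Harmonic `k (b - b0)^2` or quartic `k2 (b - b0)^2 + k4 (b - b0)^4`
#' bond potential with analytic derivative.
#'
#' @param b bond length(s), A; must be > 0.
#' @param style `"harmonic"` or `"quartic"`.
#' @param params for harmonic: list(k, b0); for quartic: list(k2, k4, b0).
#' @return list with `energy` (kcal/mol) and `deriv` (kcal/mol/A).
#' @export
bond_energy <- function(b, style = c("harmonic", "quartic"), params) {
  style <- match.arg(style)
  stopifnot(all(b > 0))
  db <- b - params$b0
  if (style == "harmonic") {
    list(energy = params$k * db^2, deriv = 2 * params$k * db)
  } else {
    list(energy = params$k2 * db^2 + params$k4 * db^4,
         deriv = 2 * params$k2 * db + 4 * params$k4 * db^3)
  }
}

# spline of ln P on the table grid; clamped outside support (with warning
# at evaluation sites beyond the grid)
.ln_spline <- function(table, periodic = FALSE) {
  g <- table$grid; p <- table$prob
  if (periodic) {
    g <- c(g, g[1] + 2 * pi)
    p <- c(p, p[1])
    stats::splinefun(g, log(p), method = "periodic")
  } else {
    stats::splinefun(g, log(p), method = "natural")
  }
}

#' Angle-class energies
#'
#' Three styles: `"flexible"` statistical potential
#' `-kB T ln(P_theta(theta)/sin(theta))` interpolated from a tabulated
#' density; `"gaussian_13"` Gaussian well on the 1-3 distance
#' `-eps exp(-(r - r0)^2 / 2 w^2)`; `"harmonic"` `ka (theta - theta0)^2`.
#' A `NULL` flexible table means the neutral density `P ~ sin(theta)`,
#' which gives a constant energy and zero force. Angles outside the table
#' support are clamped to the boundary with a warning.
#'
#' @param x angle (radians) for `flexible`/`harmonic`; 1-3 distance (A) for
#'   `gaussian_13`.
#' @param style one of `"flexible"`, `"gaussian_13"`, `"harmonic"`.
#' @param params `flexible`: list(table = list(grid, prob) or NULL,
#'   temperature_K); `gaussian_13`: list(eps, r0, w); `harmonic`:
#'   list(ka, theta0).
#' @return list with `energy` and `deriv` (w.r.t. `x`).
#' @export
angle_energy <- function(x, style = c("flexible", "gaussian_13", "harmonic"),
                         params) {
  style <- match.arg(style)
  switch(style,
    flexible = {
      stopifnot(all(x > 0), all(x < pi))
      kT <- physical_constants()$kB * params$temperature_K
      if (is.null(params$table)) {
        # P ~ sin(theta)/2: energy is the constant -kT ln(1/2)
        return(list(energy = rep(kT * log(2), length(x)),
                    deriv = rep(0, length(x))))
      }
      g <- params$table$grid
      if (any(x < g[1] | x > g[length(g)])) {
        warning("angle outside flexible-table support; clamped to boundary")
        x <- pmin(g[length(g)], pmax(g[1], x))
      }
      s <- .ln_spline(params$table)
      list(energy = -kT * (s(x) - log(sin(x))),
           deriv = -kT * (s(x, deriv = 1) - cos(x) / sin(x)))
    },
    gaussian_13 = {
      stopifnot(all(x > 0))
      z <- (x - params$r0) / params$w
      e <- -params$eps * exp(-z^2 / 2)
      list(energy = e, deriv = -e * z / params$w)
    },
    harmonic = {
      d <- x - params$theta0
      list(energy = params$ka * d^2, deriv = 2 * params$ka * d)
    })
}

#' Dihedral-class energies
#'
#' Three styles on the periodic domain (-pi, pi]: `"flexible"`
#' `-kB T ln P_d(phi)` with periodic spline interpolation (`NULL` table =
#' uniform density, flat energy); `"gaussian"`
#' `-eps exp(-dphi^2 / 2 sigma^2)` with minimum-image angular difference;
#' `"periodic"` `sum_n k_n [1 + cos(n (phi - phi0))]`.
#'
#' @param phi dihedral angle(s), radians.
#' @param style one of `"flexible"`, `"gaussian"`, `"periodic"`.
#' @param params `flexible`: list(table, temperature_K); `gaussian`:
#'   list(eps, phi0, sigma); `periodic`: list(k, n, phi0) with `k` and `n`
#'   parallel vectors of harmonics.
#' @return list with `energy` and `deriv`.
#' @export
dihedral_energy <- function(phi, style = c("flexible", "gaussian", "periodic"),
                            params) {
  style <- match.arg(style)
  switch(style,
    flexible = {
      kT <- physical_constants()$kB * params$temperature_K
      if (is.null(params$table)) {
        return(list(energy = rep(kT * log(2 * pi), length(phi)),
                    deriv = rep(0, length(phi))))
      }
      s <- .ln_spline(params$table, periodic = TRUE)
      g1 <- params$table$grid[1]
      ph <- g1 + (phi - g1) %% (2 * pi)   # map into the table period
      list(energy = -kT * s(ph), deriv = -kT * s(ph, deriv = 1))
    },
    gaussian = {
      d <- ang_diff(phi, params$phi0)
      z <- d / params$sigma
      e <- -params$eps * exp(-z^2 / 2)
      list(energy = e, deriv = -e * z / params$sigma)
    },
    periodic = {
      e <- 0; de <- 0
      for (h in seq_along(params$n)) {
        arg <- params$n[h] * (phi - params$phi0)
        e <- e + params$k[h] * (1 + cos(arg))
        de <- de - params$k[h] * params$n[h] * sin(arg)
      }
      list(energy = e, deriv = de)
    })
}

#' Structure-based native-contact (Go) energy
#'
#' `eps [5 (sigma/r)^12 - 6 (sigma/r)^10]`: minimum `-eps` at `r = sigma`.
#'
#' @param r pair distance(s), A; > 0.
#' @param sigma reference contact distance, A.
#' @param eps contact strength, kcal/mol.
#' @return list with `energy` and `deriv`.
#' @export
go_contact_energy <- function(r, sigma, eps) {
  stopifnot(all(r > 0))
  s10 <- (sigma / r)^10
  s12 <- (sigma / r)^12
  list(energy = eps * (5 * s12 - 6 * s10),
       deriv = (60 * eps / r) * (s10 - s12))
}

#' Excluded-volume energies
#'
#' `"aicg"`: purely repulsive `eps (sigma/r)^12 - (1/2)^12 eps`, zero for
#' `r >= 2 sigma` (the shift makes it vanish continuously at the cutoff).
#' `"dna"`: `eps [(sigma/r)^12 - 2 (sigma/r)^6] + eps` for `r < sigma`,
#' zero beyond (continuous at `r = sigma`).
#'
#' @param r distance(s), A; > 0.
#' @param style `"aicg"` or `"dna"`.
#' @param params list(eps, sigma).
#' @return list with `energy` and `deriv`.
#' @export
excluded_volume_energy <- function(r, style = c("aicg", "dna"), params) {
  style <- match.arg(style)
  stopifnot(all(r > 0))
  eps <- params$eps; sigma <- params$sigma
  if (style == "aicg") {
    inside <- r < 2 * sigma
    s12 <- ifelse(inside, (sigma / r)^12, 0)
    list(energy = ifelse(inside, eps * s12 - (0.5)^12 * eps, 0),
         deriv = ifelse(inside, -12 * eps * s12 / r, 0))
  } else {
    inside <- r < sigma
    s6 <- ifelse(inside, (sigma / r)^6, 0)
    list(energy = ifelse(inside, eps * (s6^2 - 2 * s6) + eps, 0),
         deriv = ifelse(inside, (-12 * eps / r) * (s6^2 - s6), 0))
  }
}

#' Hydropathy-scale (HPS) pair energy
#'
#' Ashbaugh-Hatch form: `E_LJ + (1 - lambda) eps` for
#' `r <= 2^(1/6) sigma`, `lambda E_LJ` beyond, with
#' `E_LJ = 4 eps [(sigma/r)^12 - (sigma/r)^6]`; continuous at the switch.
#'
#' @param r distance(s), A; > 0.
#' @param sigma pair diameter, A (arithmetic combination of residue values).
#' @param lambda pair hydropathy (arithmetic combination; may exceed 1).
#' @param eps well depth, kcal/mol (default model value 0.2).
#' @return list with `energy` and `deriv`.
#' @export
hps_pair_energy <- function(r, sigma, lambda, eps = 0.2) {
  stopifnot(all(r > 0))
  s6 <- (sigma / r)^6
  elj <- 4 * eps * (s6^2 - s6)
  delj <- (24 * eps / r) * (s6 - 2 * s6^2)
  core <- r <= 2^(1 / 6) * sigma
  list(energy = ifelse(core, elj + (1 - lambda) * eps, lambda * elj),
       deriv = ifelse(core, delj, lambda * delj))
}

#' Relative permittivity of salt solution
#'
#' Product `e(T) a(C)` of the empirical temperature and salt-molarity
#' polynomials: `e(T) = 249.4 - 0.788 T + 7.20e-4 T^2` and
#' `a(C) = 1 - 0.2551 C + 5.151e-2 C^2 - 6.889e-3 C^3`.
#'
#' @param temperature_K temperature (K), in (200, 400) where the fit holds.
#' @param salt_molarity salt molarity C (mol/L), >= 0.
#' @return dimensionless relative permittivity.
#' @export
relative_permittivity <- function(temperature_K, salt_molarity) {
  if (any(temperature_K <= 200 | temperature_K >= 400))
    stop("temperature outside the validity range (200, 400) K of e(T)")
  if (any(salt_molarity < 0)) stop("salt molarity must be >= 0")
  eT <- 249.4 - 0.788 * temperature_K + 7.20e-4 * temperature_K^2
  aC <- 1 - 0.2551 * salt_molarity + 5.151e-2 * salt_molarity^2 -
    6.889e-3 * salt_molarity^3
  eT * aC
}

#' Debye screening length
#'
#' `lambda_D = sqrt(kB T eps0 eps_r / (2 N_A e^2 I))` in Angstrom, with
#' the ionic strength I in mol/L.
#'
#' @param temperature_K temperature (K).
#' @param ionic_strength ionic strength I (mol/L), > 0.
#' @param eps_r relative permittivity of the solution.
#' @return Debye length in A.
#' @export
debye_length <- function(temperature_K, ionic_strength, eps_r) {
  if (any(ionic_strength <= 0))
    stop("ionic strength must be > 0 (I = 0 gives an infinite screening length)")
  cst <- physical_constants()
  num <- cst$kB_SI * temperature_K * cst$eps0 * eps_r
  den <- 2 * cst$N_A * cst$e_c^2 * ionic_strength * 1000  # mol/L -> mol/m^3
  sqrt(num / den) * 1e10
}

#' Debye-Hueckel screened electrostatic energy
#'
#' `q_i q_j k_C exp(-r/lambda_D) / (eps_r r)` in kcal/mol with the Coulomb
#' factor k_C = 332.0716 kcal A / (mol e^2); zero beyond `r_cut`.
#'
#' @param r distance(s), A; > 0.
#' @param qi,qj charges (e).
#' @param eps_r relative permittivity.
#' @param lambda_d Debye length (A).
#' @param r_cut electrostatic cutoff (A); default `Inf`.
#' @return list with `energy` and `deriv`.
#' @export
debye_huckel_energy <- function(r, qi, qj, eps_r, lambda_d, r_cut = Inf) {
  stopifnot(all(r > 0))
  kC <- physical_constants()$coulomb
  e <- kC * qi * qj * exp(-r / lambda_d) / (eps_r * r)
  de <- -e * (1 / r + 1 / lambda_d)
  inside <- r < r_cut
  list(energy = ifelse(inside, e, 0), deriv = ifelse(inside, de, 0))
}

#' Repulsive/attractive split of the Morse potential
#'
#' Full Morse `eps (1 - exp(-alpha (r - r0)))^2 - eps` split into a
#' repulsive part (the rising inner branch, zero for `r >= r0`) and an
#' attractive part (`-eps` inside `r0`, the outer branch beyond); the two
#' components sum to the full Morse everywhere.
#'
#' @param r distance(s), A; > 0.
#' @param eps Morse depth, kcal/mol.
#' @param alpha Morse width, 1/A.
#' @param r0 reference distance, A.
#' @return list with `rep`, `attr` (kcal/mol) and derivatives `drep`,
#'   `dattr` (kcal/mol/A).
#' @export
morse_components <- function(r, eps, alpha, r0) {
  stopifnot(all(r > 0))
  ex <- exp(-alpha * (r - r0))
  full <- eps * (1 - ex)^2 - eps
  dfull <- 2 * eps * alpha * ex * (1 - ex)
  inner <- r < r0
  list(rep  = ifelse(inner, full + eps, 0),
       attr = ifelse(inner, -eps, full),
       drep = ifelse(inner, dfull, 0),
       dattr = ifelse(inner, 0, dfull))
}

#' Angle modulation function of the DNA multi-body terms
#'
#' 1 inside `|dtheta| < gamma`, `1 - cos^2(pi dtheta / 2 gamma)` on
#' `gamma <= |dtheta| <= 2 gamma`, 0 beyond; continuous at both knots.
#'
#' @param dtheta angular deviation(s) from the reference, radians.
#' @param gamma modulation half-width, radians; > 0.
#' @return list with `f` in `[0, 1]` and `df` (derivative w.r.t. `dtheta`).
#' @export
angle_modulation <- function(dtheta, gamma) {
  stopifnot(gamma > 0)
  a <- abs(dtheta)
  c1 <- cos(pi * dtheta / (2 * gamma))
  f <- ifelse(a < gamma, 1, ifelse(a <= 2 * gamma, 1 - c1^2, 0))
  df <- ifelse(a >= gamma & a <= 2 * gamma,
               (pi / (2 * gamma)) * sin(pi * dtheta / gamma), 0)
  list(f = f, df = df)
}
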