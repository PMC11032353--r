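## Multi-body DNA base-base terms (stacking, base pairing, cross-stacking)
## and the PWM-based protein-DNA recognition term, with analytic Cartesian
## forces assembled by the chain rule from morse_components(),
## angle_modulation(), angle_geometry() and dihedral_geometry().

# guard for collinear angle geometry: modulation forces are zeroed (with a
# warning) when the angle is numerically undefined
.angle_ok <- function(theta, tol = 1e-6) {
  ok <- sin(theta) > tol
  if (!all(ok))
    warning("degenerate (collinear) angle geometry; modulation forces set to 0")
  ok
}

#' DNA multi-body base-base energy and forces
#'
#' Evaluates one stacking, base-pairing or cross-stacking term from site
#' coordinates. Geometry conventions (documented package choice; the site
#' tuples follow the surrounding sugar sites):
#' \itemize{
#'   \item `stack`, sites `(S1, B1, B2)`: distance `r = |B1 - B2|`,
#'     `theta_BS = angle(S1, B1, B2)`;
#'     `E = Morse_rep(r) + f(dtheta_BS) Morse_attr(r)`.
#'   \item `pair`, sites `(S1, B1, B2, S2)`: `theta1 = angle(S1, B1, B2)`,
#'     `theta2 = angle(S2, B2, B1)`, `phi_BP = dihedral(S1, B1, B2, S2)`;
#'     `E = rep + 1/2 (1 + cos dphi) f(dtheta1) f(dtheta2) attr`.
#'   \item `cross`, sites `(S1, B1, B2, S2)`: `theta3 = angle(S1, B1, B2)`,
#'     `theta_CS = angle(B1, B2, S2)`; `E = f(dtheta3) f(dtheta_CS) attr`.
#' }
#'
#' @param term `"stack"`, `"pair"` or `"cross"`.
#' @param sites coordinate matrix (3 or 4 rows x 3) in the role order above.
#' @param params list with Morse set `eps`, `alpha`, `r0`, modulation
#'   half-width `gamma`, and reference angles (`theta0` for stack;
#'   `theta1_0`, `theta2_0`, `phi0` for pair; `theta3_0`, `thetaCS_0` for
#'   cross).
#' @param box orthorhombic box lengths or NULL.
#' @return list with `energy` (kcal/mol) and `forces` (rows matching
#'   `sites`).
#' @export
dna_multibody_energy <- function(term = c("stack", "pair", "cross"),
                                 sites, params, box = NULL) {
  term <- match.arg(term)
  sites <- as.matrix(sites)
  F <- matrix(0, nrow(sites), 3)
  rowm <- function(i) sites[i, , drop = FALSE]
  # base-base distance is always between the two base rows
  bi <- if (term == "stack") 2L else 2L
  bj <- 3L
  dv <- min_image(rowm(bi) - rowm(bj), box)
  r <- sqrt(sum(dv * dv))
  mo <- morse_components(r, params$eps, params$alpha, params$r0)
  gr_r_i <- dv / r   # d r / d x_{bi}

  if (term == "stack") {
    ag <- angle_geometry(rowm(1), rowm(2), rowm(3), box)
    ok <- .angle_ok(ag$theta)
    dth <- ang_diff(ag$theta, params$theta0)
    fm <- angle_modulation(dth, params$gamma)
    e <- mo$rep + fm$f * mo$attr
    dEdr <- mo$drep + fm$f * mo$dattr
    F[2, ] <- F[2, ] - dEdr * gr_r_i
    F[3, ] <- F[3, ] + dEdr * gr_r_i
    if (ok) {
      dEdth <- fm$df * mo$attr
      F[1, ] <- F[1, ] - dEdth * ag$dthet_di
      F[2, ] <- F[2, ] - dEdth * ag$dthet_dj
      F[3, ] <- F[3, ] - dEdth * ag$dthet_dk
    }
  } else if (term == "pair") {
    a1 <- angle_geometry(rowm(1), rowm(2), rowm(3), box)
    a2 <- angle_geometry(rowm(4), rowm(3), rowm(2), box)
    dg <- dihedral_geometry(rowm(1), rowm(2), rowm(3), rowm(4), box)
    ok <- .angle_ok(a1$theta) && .angle_ok(a2$theta)
    f1 <- angle_modulation(ang_diff(a1$theta, params$theta1_0), params$gamma)
    f2 <- angle_modulation(ang_diff(a2$theta, params$theta2_0), params$gamma)
    dphi <- ang_diff(dg$phi, params$phi0)
    cfac <- 0.5 * (1 + cos(dphi))
    mod <- cfac * f1$f * f2$f
    e <- mo$rep + mod * mo$attr
    dEdr <- mo$drep + mod * mo$dattr
    F[2, ] <- F[2, ] - dEdr * gr_r_i
    F[3, ] <- F[3, ] + dEdr * gr_r_i
    if (ok) {
      dEdth1 <- cfac * f1$df * f2$f * mo$attr
      F[1, ] <- F[1, ] - dEdth1 * a1$dthet_di
      F[2, ] <- F[2, ] - dEdth1 * a1$dthet_dj
      F[3, ] <- F[3, ] - dEdth1 * a1$dthet_dk
      dEdth2 <- cfac * f1$f * f2$df * mo$attr
      F[4, ] <- F[4, ] - dEdth2 * a2$dthet_di
      F[3, ] <- F[3, ] - dEdth2 * a2$dthet_dj
      F[2, ] <- F[2, ] - dEdth2 * a2$dthet_dk
      dEdphi <- -0.5 * sin(dphi) * f1$f * f2$f * mo$attr
      F[1, ] <- F[1, ] - dEdphi * dg$dphi_di
      F[2, ] <- F[2, ] - dEdphi * dg$dphi_dj
      F[3, ] <- F[3, ] - dEdphi * dg$dphi_dk
      F[4, ] <- F[4, ] - dEdphi * dg$dphi_dl
    }
  } else { # cross
    a3 <- angle_geometry(rowm(1), rowm(2), rowm(3), box)
    acs <- angle_geometry(rowm(2), rowm(3), rowm(4), box)
    ok <- .angle_ok(a3$theta) && .angle_ok(acs$theta)
    f3 <- angle_modulation(ang_diff(a3$theta, params$theta3_0), params$gamma)
    fcs <- angle_modulation(ang_diff(acs$theta, params$thetaCS_0),
                            params$gamma)
    mod <- f3$f * fcs$f
    e <- mod * mo$attr
    dEdr <- mod * mo$dattr
    F[2, ] <- F[2, ] - dEdr * gr_r_i
    F[3, ] <- F[3, ] + dEdr * gr_r_i
    if (ok) {
      dEdth3 <- f3$df * fcs$f * mo$attr
      F[1, ] <- F[1, ] - dEdth3 * a3$dthet_di
      F[2, ] <- F[2, ] - dEdth3 * a3$dthet_dj
      F[3, ] <- F[3, ] - dEdth3 * a3$dthet_dk
      dEdcs <- f3$f * fcs$df * mo$attr
      F[2, ] <- F[2, ] - dEdcs * acs$dthet_di
      F[3, ] <- F[3, ] - dEdcs * acs$dthet_dj
      F[4, ] <- F[4, ] - dEdcs * acs$dthet_dk
    }
  }
  list(energy = as.numeric(e), forces = F)
}

#' PWM-based protein-DNA recognition energy and forces
#'
#' Sum over (base, DNA-binding C-alpha, PWM column) tuples of a Gaussian
#' in the base/C-alpha distance modulated by three angle factors:
#' `theta1 = angle(S, B, C)`, `theta2 = angle(B, C, C_prev)`,
#' `theta3 = angle(B, C, C_next)`. Each tuple contributes the direct term
#' plus the complementary-base partner term, i.e. the Gaussian depth is
#' `eps_table[base, col] + eps_table[complement(base), col]`.
#'
#' @param coords full coordinate matrix (N x 3).
#' @param sites data frame with integer columns `b` (base site), `s` (its
#'   sugar), `c` (C-alpha), `cm` (preceding C-alpha), `cp` (following
#'   C-alpha), plus `base` (character A/C/G/T) and `col` (PWM column).
#' @param params PWMcos parameter list: `eps_table` (matrix with rownames
#'   A/C/G/T, one column per PWM column), `w`, `r0`, `gamma`, `theta1_0`,
#'   `theta2_0`, `theta3_0`.
#' @param box orthorhombic box lengths or NULL.
#' @return list with `energy` and `forces` (N x 3).
#' @export
pwmcos_energy <- function(coords, sites, params, box = NULL) {
  F <- matrix(0, nrow(coords), 3)
  etot <- 0
  if (is.null(params$eps_table))
    stop("PWMcos requires an eps_table (depth per base type and PWM column)")
  for (t in seq_len(nrow(sites))) {
    st <- sites[t, ]
    base <- as.character(st$base)
    comp <- .dna_complement[[base]]
    tab <- params$eps_table
    if (!(base %in% rownames(tab)) || st$col > ncol(tab))
      stop(sprintf("missing PWMcos eps entry for (%s, column %d)",
                   base, st$col))
    eps_sum <- unname(tab[base, st$col] + tab[comp, st$col])
    iB <- st$b; iS <- st$s; iC <- st$c; iCm <- st$cm; iCp <- st$cp
    dv <- min_image(coords[iB, , drop = FALSE] - coords[iC, , drop = FALSE],
                    box)
    r <- sqrt(sum(dv * dv))
    z <- (r - params$r0) / params$w
    g <- exp(-z^2 / 2)
    dg <- -g * z / params$w
    a1 <- angle_geometry(coords[iS, , drop = FALSE],
                         coords[iB, , drop = FALSE],
                         coords[iC, , drop = FALSE], box)
    a2 <- angle_geometry(coords[iB, , drop = FALSE],
                         coords[iC, , drop = FALSE],
                         coords[iCm, , drop = FALSE], box)
    a3 <- angle_geometry(coords[iB, , drop = FALSE],
                         coords[iC, , drop = FALSE],
                         coords[iCp, , drop = FALSE], box)
    ok <- .angle_ok(a1$theta) && .angle_ok(a2$theta) && .angle_ok(a3$theta)
    f1 <- angle_modulation(ang_diff(a1$theta, params$theta1_0), params$gamma)
    f2 <- angle_modulation(ang_diff(a2$theta, params$theta2_0), params$gamma)
    f3 <- angle_modulation(ang_diff(a3$theta, params$theta3_0), params$gamma)
    e <- -eps_sum * g * f1$f * f2$f * f3$f
    etot <- etot + e
    # radial part
    dEdr <- -eps_sum * dg * f1$f * f2$f * f3$f
    gr <- dv / r
    F[iB, ] <- F[iB, ] - dEdr * gr
    F[iC, ] <- F[iC, ] + dEdr * gr
    if (ok && e != 0) {
      acc <- function(idx, grad, dEdth) {
        F[idx, ] <<- F[idx, ] - dEdth * grad
      }
      dEdth1 <- -eps_sum * g * f1$df * f2$f * f3$f
      acc(iS, a1$dthet_di, dEdth1); acc(iB, a1$dthet_dj, dEdth1)
      acc(iC, a1$dthet_dk, dEdth1)
      dEdth2 <- -eps_sum * g * f1$f * f2$df * f3$f
      acc(iB, a2$dthet_di, dEdth2); acc(iC, a2$dthet_dj, dEdth2)
      acc(iCm, a2$dthet_dk, dEdth2)
      dEdth3 <- -eps_sum * g * f1$f * f2$f * f3$df
      acc(iB, a3$dthet_di, dEdth3); acc(iC, a3$dthet_dj, dEdth3)
      acc(iCp, a3$dthet_dk, dEdth3)
    }
  }
  list(energy = etot, forces = F)
}
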