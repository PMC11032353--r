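## Whole-system energy and force evaluation (reference R path). The
## per-class pair interactions are read from the neighbor lists; bonded
## and multi-body terms come straight from the topology. Interaction
## applicability by particle kind: HPS acts between protein beads when at
## least one is disordered; the structure-based excluded volume acts
## between ordered-ordered protein pairs and any pair involving DNA
## (DNA-DNA pairs use the DNA excluded-volume form); electrostatics act
## between all charged pairs.

# scatter-add row contributions into F
.add_force <- function(F, idx, contrib) {
  rs <- rowsum(contrib, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(rs))
  F[rows, ] <- F[rows, ] + rs
  F
}

# pair-force accumulation from dE/dr: F_i -= dEdr * unit(i - j)
.pair_forces <- function(F, x, box, i, j, dEdr) {
  d <- min_image(x[i, , drop = FALSE] - x[j, , drop = FALSE], box)
  r <- row_norm(d)
  u <- d / r
  F <- .add_force(F, i, -dEdr * u)
  .add_force(F, j, dEdr * u)
}

#' Total energy and forces
#'
#' Evaluates every term class of the force field for a topology/state
#' pair: bonded terms (bonds, angles, dihedrals), native contacts, the
#' per-class nonbonded interactions truncated at their cutoffs
#' (excluded volume, HPS, Debye-Hueckel electrostatics), the DNA
#' multi-body terms and the protein-DNA recognition term. All pair
#' vectors use the minimum-image convention.
#'
#' @param topology a `cg_topology`.
#' @param state a `cg_state`.
#' @param params a [cg_parameters()] set.
#' @param nblists neighbor lists from [build_neighbor_lists()]; must be
#'   current for `state` (a stale list is rejected).
#' @param check_stale set FALSE to skip the staleness rejection (used by
#'   the finite-difference tests which displace coordinates).
#' @return list with `energies` (named per-class vector, kcal/mol) and
#'   `forces` (N x 3, kcal/mol/A).
#' @export
total_energy_forces <- function(topology, state, params, nblists,
                                check_stale = TRUE) {
  if (check_stale && needs_rebuild(state, nblists))
    stop("stale neighbor lists: rebuild required before evaluating")
  x <- state$coords; box <- state$box
  np <- nrow(x)
  F <- matrix(0, np, 3)
  en <- c(bond = 0, angle = 0, dihedral = 0, go = 0, exv = 0, hps = 0,
          ele = 0, dna_stack = 0, dna_pair = 0, dna_cross = 0, pwmcos = 0)
  kind <- topology$particles$kind
  Tk <- params$environment$temperature_K

  ## bonds
  b <- topology$bonds
  if (!is.null(b) && nrow(b) > 0) {
    d <- min_image(x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE], box)
    r <- row_norm(d)
    e <- numeric(nrow(b)); de <- numeric(nrow(b))
    for (st in unique(b$style)) {
      sel <- b$style == st
      res <- if (st == "harmonic")
        bond_energy(r[sel], "harmonic", list(k = b$k[sel], b0 = b$b0[sel]))
      else
        bond_energy(r[sel], "quartic",
                    list(k2 = b$k2[sel], k4 = b$k4[sel], b0 = b$b0[sel]))
      e[sel] <- res$energy; de[sel] <- res$deriv
    }
    en["bond"] <- sum(e)
    F <- .pair_forces(F, x, box, b$i, b$j, de)
  }

  ## angles (flexible/harmonic act on theta; gaussian_13 on the 1-3 distance)
  a <- topology$angles
  if (!is.null(a) && nrow(a) > 0) {
    for (st in unique(a$style)) {
      sel <- which(a$style == st)
      if (st == "gaussian_13") {
        res <- NULL
        d13 <- min_image(x[a$i[sel], , drop = FALSE] -
                           x[a$k[sel], , drop = FALSE], box)
        r13 <- row_norm(d13)
        res <- angle_energy(r13, "gaussian_13",
                            list(eps = a$eps[sel], r0 = a$r0[sel],
                                 w = a$w[sel]))
        en["angle"] <- en["angle"] + sum(res$energy)
        F <- .pair_forces(F, x, box, a$i[sel], a$k[sel], res$deriv)
      } else {
        ag <- angle_geometry(x[a$i[sel], , drop = FALSE],
                             x[a$j[sel], , drop = FALSE],
                             x[a$k[sel], , drop = FALSE], box)
        if (st == "flexible") {
          dE <- numeric(length(sel)); ee <- numeric(length(sel))
          for (tb in unique(a$table[sel])) {
            ss <- a$table[sel] == tb
            res <- angle_energy(ag$theta[ss], "flexible",
                                list(table = params$flexible$angle[[tb]],
                                     temperature_K = Tk))
            ee[ss] <- res$energy; dE[ss] <- res$deriv
          }
        } else {
          res <- angle_energy(ag$theta, "harmonic",
                              list(ka = a$ka[sel], theta0 = a$theta0[sel]))
          ee <- res$energy; dE <- res$deriv
        }
        en["angle"] <- en["angle"] + sum(ee)
        F <- .add_force(F, a$i[sel], -dE * ag$dthet_di)
        F <- .add_force(F, a$j[sel], -dE * ag$dthet_dj)
        F <- .add_force(F, a$k[sel], -dE * ag$dthet_dk)
      }
    }
  }

  ## dihedrals
  dh <- topology$dihedrals
  if (!is.null(dh) && nrow(dh) > 0) {
    dg <- dihedral_geometry(x[dh$i, , drop = FALSE], x[dh$j, , drop = FALSE],
                            x[dh$k, , drop = FALSE], x[dh$l, , drop = FALSE],
                            box)
    dE <- numeric(nrow(dh)); ee <- numeric(nrow(dh))
    for (st in unique(dh$style)) {
      sel <- which(dh$style == st)
      if (st == "flexible") {
        for (tb in unique(dh$table[sel])) {
          ss <- sel[dh$table[sel] == tb]
          res <- dihedral_energy(dg$phi[ss], "flexible",
                                 list(table = params$flexible$dihedral[[tb]],
                                      temperature_K = Tk))
          ee[ss] <- res$energy; dE[ss] <- res$deriv
        }
      } else if (st == "gaussian") {
        res <- dihedral_energy(dg$phi[sel], "gaussian",
                               list(eps = dh$eps[sel], phi0 = dh$phi0[sel],
                                    sigma = dh$sigma[sel]))
        ee[sel] <- res$energy; dE[sel] <- res$deriv
      } else {
        # periodic: one harmonic per row (k, n scalars per row)
        arg <- dh$n[sel] * (dg$phi[sel] - dh$phi0[sel])
        ee[sel] <- dh$kp[sel] * (1 + cos(arg))
        dE[sel] <- -dh$kp[sel] * dh$n[sel] * sin(arg)
      }
    }
    en["dihedral"] <- sum(ee)
    F <- .add_force(F, dh$i, -dE * dg$dphi_di)
    F <- .add_force(F, dh$j, -dE * dg$dphi_dj)
    F <- .add_force(F, dh$k, -dE * dg$dphi_dk)
    F <- .add_force(F, dh$l, -dE * dg$dphi_dl)
  }

  ## native contacts (Go)
  gc <- topology$native_contacts
  if (!is.null(gc) && nrow(gc) > 0) {
    d <- min_image(x[gc$i, , drop = FALSE] - x[gc$j, , drop = FALSE], box)
    r <- row_norm(d)
    res <- go_contact_energy(r, gc$sigma, gc$eps)
    en["go"] <- sum(res$energy)
    F <- .pair_forces(F, x, box, gc$i, gc$j, res$deriv)
  }

  ## residue tables for pair combination
  rt <- params$residues
  ridx <- match(topology$particles$code, rt$code)
  psig <- rt$sigma[ridx]; plam <- rt$lambda[ridx]
  dsig <- unname(params$dna$exv$sigma[topology$particles$code])
  is_protein <- kind %in% c("ordered_protein", "disordered_protein")
  is_dna <- !is_protein

  ## excluded volume class
  pe <- nblists$pairs$exv
  if (nrow(pe) > 0) {
    both_dna <- is_dna[pe$i] & is_dna[pe$j]
    aicg_sel <- (!both_dna) &
      !(is_protein[pe$i] & is_protein[pe$j] &
          (kind[pe$i] == "disordered_protein" |
             kind[pe$j] == "disordered_protein"))
    r <- pmin(pe$r, Inf)
    d <- min_image(x[pe$i, , drop = FALSE] - x[pe$j, , drop = FALSE], box)
    r <- row_norm(d)
    within <- r < params$cutoffs$exv
    if (any(aicg_sel & within)) {
      sel <- which(aicg_sel & within)
      sig <- ifelse(is_protein[pe$i[sel]], psig[pe$i[sel]],
                    dsig[pe$i[sel]]) / 2 +
        ifelse(is_protein[pe$j[sel]], psig[pe$j[sel]], dsig[pe$j[sel]]) / 2
      res <- excluded_volume_energy(r[sel], "aicg",
                                    list(eps = params$aicg$eps_exv,
                                         sigma = sig))
      en["exv"] <- en["exv"] + sum(res$energy)
      F <- .pair_forces(F, x, box, pe$i[sel], pe$j[sel], res$deriv)
    }
    if (any(both_dna & within)) {
      sel <- which(both_dna & within)
      sig <- (dsig[pe$i[sel]] + dsig[pe$j[sel]]) / 2
      res <- excluded_volume_energy(r[sel], "dna",
                                    list(eps = params$dna$exv$eps,
                                         sigma = sig))
      en["exv"] <- en["exv"] + sum(res$energy)
      F <- .pair_forces(F, x, box, pe$i[sel], pe$j[sel], res$deriv)
    }
  }

  ## HPS class
  ph <- nblists$pairs$hps
  if (nrow(ph) > 0) {
    app <- is_protein[ph$i] & is_protein[ph$j] &
      (kind[ph$i] == "disordered_protein" | kind[ph$j] == "disordered_protein")
    d <- min_image(x[ph$i, , drop = FALSE] - x[ph$j, , drop = FALSE], box)
    r <- row_norm(d)
    sel <- which(app & r < params$cutoffs$hps)
    if (length(sel)) {
      sig <- (psig[ph$i[sel]] + psig[ph$j[sel]]) / 2
      lam <- (plam[ph$i[sel]] + plam[ph$j[sel]]) / 2
      res <- hps_pair_energy(r[sel], sig, lam, params$hps$epsilon)
      en["hps"] <- sum(res$energy)
      F <- .pair_forces(F, x, box, ph$i[sel], ph$j[sel], res$deriv)
    }
  }

  ## electrostatics
  pel <- nblists$pairs$ele
  if (nrow(pel) > 0) {
    epsr <- relative_permittivity(Tk, params$environment$salt_molarity)
    lam_d <- debye_length(Tk, params$environment$ionic_strength, epsr)
    q <- topology$particles$charge
    d <- min_image(x[pel$i, , drop = FALSE] - x[pel$j, , drop = FALSE], box)
    r <- row_norm(d)
    res <- debye_huckel_energy(r, q[pel$i], q[pel$j], epsr, lam_d,
                               r_cut = params$cutoffs$ele)
    en["ele"] <- sum(res$energy)
    F <- .pair_forces(F, x, box, pel$i, pel$j, res$deriv)
  }

  ## DNA multi-body terms
  eval_mb <- function(df, term, idx_cols, par_fn) {
    if (is.null(df) || nrow(df) == 0) return(invisible())
    for (t in seq_len(nrow(df))) {
      idx <- as.integer(df[t, idx_cols])
      res <- dna_multibody_energy(term, x[idx, , drop = FALSE],
                                  par_fn(df[t, ]), box)
      en[paste0("dna_", term)] <<- en[paste0("dna_", term)] + res$energy
      F[idx, ] <<- F[idx, ] + res$forces
    }
  }
  eval_mb(topology$dna_stack, "stack", c("s1", "b1", "b2"), function(rw)
    list(eps = rw$eps, alpha = rw$alpha, r0 = rw$r0, theta0 = rw$theta0,
         gamma = rw$gamma))
  eval_mb(topology$dna_pair, "pair", c("s1", "b1", "b2", "s2"), function(rw)
    list(eps = rw$eps, alpha = rw$alpha, r0 = rw$r0,
         theta1_0 = rw$theta1_0, theta2_0 = rw$theta2_0, phi0 = rw$phi0,
         gamma = rw$gamma))
  eval_mb(topology$dna_cross, "cross", c("s1", "b1", "b2", "s2"), function(rw)
    list(eps = rw$eps, alpha = rw$alpha, r0 = rw$r0,
         theta3_0 = rw$theta3_0, thetaCS_0 = rw$thetaCS_0, gamma = rw$gamma))

  ## protein-DNA recognition
  pw <- topology$pwmcos_sites
  if (!is.null(pw) && nrow(pw) > 0) {
    sel <- nblists$pairs$pwmcos
    if (length(sel)) {
      res <- pwmcos_energy(x, pw[sel, , drop = FALSE], params$pwmcos, box)
      en["pwmcos"] <- res$energy
      F <- F + res$forces
    }
  }

  list(energies = en, forces = F)
}
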