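## Topology builders: residue-level protein chains (1 bead/residue, HPS or
## structure-based model per region), three-site-per-nucleotide duplex DNA,
## native-contact extraction from reference heavy-atom structures, and
## system replication.

.kinds <- c("ordered_protein", "disordered_protein",
            "dna_phosphate", "dna_sugar", "dna_base")
.bond_styles <- c("harmonic", "quartic")
.angle_styles <- c("flexible", "gaussian_13", "harmonic")
.dihedral_styles <- c("flexible", "gaussian", "periodic")

.empty_bonds <- function() data.frame(i = integer(), j = integer(),
  style = character(), k = numeric(), k2 = numeric(), k4 = numeric(),
  b0 = numeric(), stringsAsFactors = FALSE)
.empty_angles <- function() data.frame(i = integer(), j = integer(),
  k = integer(), style = character(), table = character(), eps = numeric(),
  r0 = numeric(), w = numeric(), ka = numeric(), theta0 = numeric(),
  stringsAsFactors = FALSE)
.empty_dihedrals <- function() data.frame(i = integer(), j = integer(),
  k = integer(), l = integer(), style = character(), table = character(),
  eps = numeric(), phi0 = numeric(), sigma = numeric(), kp = numeric(),
  n = numeric(), stringsAsFactors = FALSE)
.empty_contacts <- function() data.frame(i = integer(), j = integer(),
  sigma = numeric(), eps = numeric(), stringsAsFactors = FALSE)

# sort term rows so that rows of the same style are contiguous,
# mirroring the sequential per-style parameter layout of the engine
.style_contiguous <- function(df) {
  if (nrow(df) == 0 || is.null(df$style)) return(df)
  df[order(match(df$style, unique(df$style))), , drop = FALSE]
}

#' Construct a CG topology object
#'
#' Low-level constructor; the builders [build_protein_topology()] and
#' [build_dsdna_topology()] are the usual entry points. Particle indices
#' are 1-based throughout.
#'
#' @param particles data frame with columns `chain_id`, `residue_index`,
#'   `kind` (one of ordered_protein, disordered_protein, dna_phosphate,
#'   dna_sugar, dna_base), `code`, `charge`, `mass`.
#' @param bonds,angles,dihedrals,native_contacts term tables (see the
#'   `.empty_*` templates for columns); styles must come from the allowed
#'   sets and rows of one style are stored contiguously.
#' @param dna_stack,dna_pair,dna_cross,pwmcos_sites multi-body term tables.
#' @return object of class `cg_topology`.
#' @export
cg_topology <- function(particles,
                        bonds = .empty_bonds(),
                        angles = .empty_angles(),
                        dihedrals = .empty_dihedrals(),
                        native_contacts = .empty_contacts(),
                        dna_stack = NULL, dna_pair = NULL, dna_cross = NULL,
                        pwmcos_sites = NULL) {
  top <- structure(list(
    particles = particles,
    bonds = .style_contiguous(bonds),
    angles = .style_contiguous(angles),
    dihedrals = .style_contiguous(dihedrals),
    native_contacts = native_contacts,
    dna_stack = dna_stack, dna_pair = dna_pair, dna_cross = dna_cross,
    pwmcos_sites = pwmcos_sites
  ), class = "cg_topology")
  validate_topology(top)
}

#' Number of particles in a topology
#' @param topology a `cg_topology`.
#' @return integer count.
#' @export
n_particles <- function(topology) nrow(topology$particles)

#' Chain membership of a topology
#' @param topology a `cg_topology`.
#' @return named list mapping chain id to particle indices.
#' @export
chain_members <- function(topology) {
  split(seq_len(nrow(topology$particles)), topology$particles$chain_id)
}

#' Validate a topology
#'
#' Checks: all term indices within the particle count; indices within one
#' tuple distinct; style tags from the allowed sets; same-style rows
#' contiguous; DNA multi-body terms reference only DNA site kinds with
#' base rows on `dna_base` particles.
#'
#' @param top a `cg_topology`.
#' @return `top` invisibly; stops on violation.
#' @export
validate_topology <- function(top) {
  np <- nrow(top$particles)
  stopifnot(all(top$particles$kind %in% .kinds))
  chk_idx <- function(df, cols, what) {
    if (is.null(df) || nrow(df) == 0) return(invisible())
    m <- as.matrix(df[, cols, drop = FALSE])
    if (any(m < 1) || any(m > np))
      stop(what, ": particle index out of range")
    dup <- FALSE
    for (a in seq_len(ncol(m) - 1))
      for (b in (a + 1):ncol(m))
        dup <- dup || any(m[, a] == m[, b])
    if (dup) stop(what, ": indices within a term must be distinct")
  }
  chk_style <- function(df, allowed, what) {
    if (is.null(df) || nrow(df) == 0) return(invisible())
    if (!all(df$style %in% allowed))
      stop(what, ": unknown style tag")
    r <- rle(df$style)
    if (anyDuplicated(r$values))
      stop(what, ": rows of one style must be stored contiguously")
  }
  chk_idx(top$bonds, c("i", "j"), "bonds")
  chk_idx(top$angles, c("i", "j", "k"), "angles")
  chk_idx(top$dihedrals, c("i", "j", "k", "l"), "dihedrals")
  chk_idx(top$native_contacts, c("i", "j"), "native_contacts")
  chk_style(top$bonds, .bond_styles, "bonds")
  chk_style(top$angles, .angle_styles, "angles")
  chk_style(top$dihedrals, .dihedral_styles, "dihedrals")
  kind <- top$particles$kind
  dna_kinds <- c("dna_phosphate", "dna_sugar", "dna_base")
  for (nm in c("dna_stack", "dna_pair", "dna_cross")) {
    df <- top[[nm]]
    if (is.null(df) || nrow(df) == 0) next
    idx_cols <- intersect(c("s1", "b1", "b2", "s2"), names(df))
    chk_idx(df, idx_cols, nm)
    if (!all(kind[as.matrix(df[, idx_cols])] %in% dna_kinds))
      stop(nm, ": sites must be DNA kinds")
    if (!all(kind[df$b1] == "dna_base") || !all(kind[df$b2] == "dna_base"))
      stop(nm, ": b1/b2 must be dna_base sites")
  }
  invisible(top)
}

#' @export
print.cg_topology <- function(x, ...) {
  nterm <- function(df) if (is.null(df)) 0L else nrow(df)
  cat("<cg_topology>\n")
  cat(sprintf("  %d particles in %d chains\n", nrow(x$particles),
              length(unique(x$particles$chain_id))))
  cat(sprintf("  bonds %d | angles %d | dihedrals %d | contacts %d\n",
              nterm(x$bonds), nterm(x$angles), nterm(x$dihedrals),
              nterm(x$native_contacts)))
  cat(sprintf("  dna stack/pair/cross %d/%d/%d | pwmcos %d\n",
              nterm(x$dna_stack), nterm(x$dna_pair), nterm(x$dna_cross),
              nterm(x$pwmcos_sites)))
  invisible(x)
}

#' Build a protein chain topology
#'
#' One CG bead per residue. Each region of the chain is assigned a model:
#' `"HPS"` (disordered; bonds only) or `"AICG2+"` (ordered; harmonic bonds,
#' statistical flexible angles/dihedrals, 1-3 Gaussian wells and Gaussian
#' dihedral corrections). Bonded terms that span a region boundary use the
#' HPS bond. Charges, masses and diameters come from the residue table in
#' `params`.
#'
#' @param sequence character string or vector of 1-letter residue codes.
#' @param region_models list of `list(range = c(from, to), model = ...)`
#'   in residue numbering starting at `first_residue`; ranges must tile
#'   the sequence exactly without overlap.
#' @param params a [cg_parameters()] set.
#' @param first_residue residue number of the first sequence position.
#' @param chain_id chain identifier for the particles.
#' @return a `cg_topology`.
#' @export
build_protein_topology <- function(sequence, region_models = NULL,
                                   params = cg_parameters(),
                                   first_residue = 1L, chain_id = 1L) {
  seqv <- if (length(sequence) == 1 && nchar(sequence[1]) > 1)
    strsplit(sequence, "")[[1]] else as.character(sequence)
  n <- length(seqv)
  res_ids <- seq.int(first_residue, length.out = n)
  if (is.null(region_models))
    region_models <- list(list(range = range(res_ids), model = "HPS"))
  # validate coverage
  covered <- rep(NA_character_, n)
  for (rm in region_models) {
    if (!rm$model %in% c("HPS", "AICG2+"))
      stop("unknown region model: ", rm$model)
    sel <- res_ids >= rm$range[1] & res_ids <= rm$range[2]
    if (!any(sel)) stop("region range [", rm$range[1], ", ", rm$range[2],
                        "] lies outside the sequence")
    if (any(!is.na(covered[sel])))
      stop("overlapping region ranges at residues ",
           paste(range(res_ids[sel][!is.na(covered[sel])]), collapse = "-"))
    covered[sel] <- rm$model
  }
  if (anyNA(covered))
    stop("region ranges do not cover the sequence; gap at residues ",
         paste(range(res_ids[is.na(covered)]), collapse = "-"))
  rw <- .residue_row(params, seqv)
  particles <- data.frame(
    chain_id = chain_id, residue_index = res_ids,
    kind = ifelse(covered == "AICG2+", "ordered_protein",
                  "disordered_protein"),
    code = seqv, charge = rw$charge, mass = rw$mass,
    stringsAsFactors = FALSE)
  ordered <- covered == "AICG2+"
  bonds <- .empty_bonds()
  if (n > 1) {
    i <- 1:(n - 1); j <- 2:n
    aicg_bond <- ordered[i] & ordered[j]
    bonds <- data.frame(i = i, j = j, style = "harmonic",
      k = ifelse(aicg_bond, params$aicg$kb, params$hps$kb),
      k2 = NA_real_, k4 = NA_real_,
      b0 = ifelse(aicg_bond, params$aicg$b0, params$hps$b0),
      stringsAsFactors = FALSE)
  }
  angles <- .empty_angles(); dihedrals <- .empty_dihedrals()
  if (n > 2) {
    i <- 1:(n - 2); j <- 2:(n - 1); k <- 3:n
    inreg <- ordered[i] & ordered[j] & ordered[k]
    if (any(inreg)) {
      ii <- i[inreg]; jj <- j[inreg]; kk <- k[inreg]
      g13 <- params$aicg$g13
      angles <- rbind(
        data.frame(i = ii, j = jj, k = kk, style = "flexible",
                   table = seqv[jj], eps = NA_real_, r0 = NA_real_,
                   w = NA_real_, ka = NA_real_, theta0 = NA_real_,
                   stringsAsFactors = FALSE),
        data.frame(i = ii, j = jj, k = kk, style = "gaussian_13",
                   table = NA_character_, eps = g13$eps, r0 = g13$r0,
                   w = g13$w, ka = NA_real_, theta0 = NA_real_,
                   stringsAsFactors = FALSE))
    }
  }
  if (n > 3) {
    i <- 1:(n - 3); j <- 2:(n - 2); k <- 3:(n - 1); l <- 4:n
    inreg <- ordered[i] & ordered[j] & ordered[k] & ordered[l]
    if (any(inreg)) {
      ii <- i[inreg]; jj <- j[inreg]; kk <- k[inreg]; ll <- l[inreg]
      dh <- params$aicg$dihedral
      dihedrals <- rbind(
        data.frame(i = ii, j = jj, k = kk, l = ll, style = "flexible",
                   table = seqv[jj], eps = NA_real_, phi0 = NA_real_,
                   sigma = NA_real_, kp = NA_real_, n = NA_real_,
                   stringsAsFactors = FALSE),
        data.frame(i = ii, j = jj, k = kk, l = ll, style = "gaussian",
                   table = NA_character_, eps = dh$eps, phi0 = dh$phi0,
                   sigma = dh$sigma, kp = NA_real_, n = NA_real_,
                   stringsAsFactors = FALSE))
    }
  }
  cg_topology(particles, bonds, angles, dihedrals)
}

#' Reference structure for native-contact extraction
#'
#' Per-residue heavy-atom coordinates plus a representative bead
#' coordinate (default: the atom centroid) used for the contact distance.
#'
#' @param residue_index integer residue numbers.
#' @param atoms list (one entry per residue) of heavy-atom coordinate
#'   matrices (m x 3, A).
#' @param bead optional matrix (n x 3) of bead coordinates.
#' @return object of class `cg_reference`.
#' @export
reference_structure <- function(residue_index, atoms, bead = NULL) {
  stopifnot(length(residue_index) == length(atoms))
  for (q in seq_along(atoms)) {
    a <- atoms[[q]]
    if (is.null(a) || !is.matrix(a) || nrow(a) == 0 || !all(is.finite(a)))
      stop("missing or non-finite heavy-atom coordinates for residue ",
           residue_index[q])
  }
  if (is.null(bead))
    bead <- t(vapply(atoms, colMeans, numeric(3)))
  structure(list(residue_index = residue_index, atoms = atoms, bead = bead),
            class = "cg_reference")
}

#' Extract native contacts from a reference structure
#'
#' A residue pair forms a native contact when any two of their heavy atoms
#' are within `cutoff` of each other; the contact distance `sigma` is the
#' bead-bead distance in the reference. Pairs closer than `min_seq_sep`
#' in sequence are skipped (they are covered by bonded terms).
#'
#' @param ref a [reference_structure()].
#' @param cutoff heavy-atom contact cutoff (A), default 4.5.
#' @param min_seq_sep minimum |i - j| in residue numbering, default 3.
#' @param eps contact strength assigned to every contact (kcal/mol).
#' @return data frame with columns `i`, `j` (residue numbers, i < j),
#'   `sigma`, `eps`.
#' @export
extract_native_contacts <- function(ref, cutoff = 4.5, min_seq_sep = 3L,
                                    eps = 0.3) {
  n <- length(ref$residue_index)
  out <- .empty_contacts()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (abs(ref$residue_index[b] - ref$residue_index[a]) < min_seq_sep)
        next
      A <- ref$atoms[[a]]; B <- ref$atoms[[b]]
      # min cross distance between the two heavy-atom sets
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
      if (min(d2) <= cutoff^2) {
        sig <- sqrt(sum((ref$bead[a, ] - ref$bead[b, ])^2))
        out <- rbind(out, data.frame(i = ref$residue_index[a],
                                     j = ref$residue_index[b],
                                     sigma = sig, eps = eps))
      }
    }
  }
  out
}

#' Attach native contacts to a topology
#'
#' Maps residue-numbered contacts onto particle indices of one chain and
#' stores them in the topology (replacing any previous contact list).
#'
#' @param topology a `cg_topology`.
#' @param contacts data frame from [extract_native_contacts()].
#' @param chain_id chain whose residue numbering the contacts use.
#' @return the updated `cg_topology`.
#' @export
set_native_contacts <- function(topology, contacts, chain_id = 1L) {
  pt <- topology$particles
  sel <- which(pt$chain_id == chain_id)
  idx <- function(res) {
    m <- sel[match(res, pt$residue_index[sel])]
    if (anyNA(m)) stop("contact references unknown residue(s): ",
                       paste(res[is.na(m)], collapse = ", "))
    m
  }
  topology$native_contacts <- data.frame(
    i = idx(contacts$i), j = idx(contacts$j),
    sigma = contacts$sigma, eps = contacts$eps)
  validate_topology(topology)
}

#' Build a double-stranded DNA topology
#'
#' Three sites per nucleotide (phosphate, sugar, base) with the
#' 5'-terminal phosphate of each strand omitted, giving `3 n - 1` sites
#' per strand. The complementary strand is generated automatically.
#' Bonds are quartic; backbone and base angles harmonic; backbone
#' dihedrals carry a periodic term plus a Gaussian correction; stacking,
#' Watson-Crick pairing and cross-stacking tuples are emitted with the
#' Morse/modulation parameters from `params$dna`. Phosphates carry the
#' phosphate charge.
#'
#' @param sequence string of A/C/G/T (5' to 3' of the first strand).
#' @param params a [cg_parameters()] set.
#' @param chain_ids length-2 chain identifiers for the two strands.
#' @return a `cg_topology`.
#' @export
build_dsdna_topology <- function(sequence, params = cg_parameters(),
                                 chain_ids = c(1L, 2L)) {
  seqv <- if (length(sequence) == 1 && nchar(sequence[1]) > 1)
    strsplit(toupper(sequence), "")[[1]] else toupper(as.character(sequence))
  if (!all(seqv %in% c("A", "C", "G", "T")))
    stop("invalid base symbol(s): ",
         paste(unique(seqv[!seqv %in% c("A", "C", "G", "T")]), collapse = ","))
  n <- length(seqv)
  dn <- params$dna
  strand_sites <- function(bases, chain) {
    # site layout per strand (5'->3'): S1 B1 [P2 S2 B2] [P3 S3 B3] ...
    kind <- character(0); code <- character(0); resi <- integer(0)
    Sidx <- integer(n); Bidx <- integer(n); Pidx <- rep(NA_integer_, n)
    pos <- 0L
    for (t in seq_len(n)) {
      if (t > 1) { pos <- pos + 1L; Pidx[t] <- pos
        kind <- c(kind, "dna_phosphate"); code <- c(code, "P")
        resi <- c(resi, t) }
      pos <- pos + 1L; Sidx[t] <- pos
      kind <- c(kind, "dna_sugar"); code <- c(code, "S"); resi <- c(resi, t)
      pos <- pos + 1L; Bidx[t] <- pos
      kind <- c(kind, "dna_base"); code <- c(code, bases[t])
      resi <- c(resi, t)
    }
    mass <- unname(dn$site_mass[ifelse(code %in% c("P", "S"), code, code)])
    charge <- ifelse(kind == "dna_phosphate", dn$phosphate_charge, 0)
    list(particles = data.frame(chain_id = chain, residue_index = resi,
           kind = kind, code = code, charge = charge, mass = mass,
           stringsAsFactors = FALSE),
         S = Sidx, B = Bidx, P = Pidx)
  }
  s1 <- strand_sites(seqv, chain_ids[1])
  comp <- unname(.dna_complement[rev(seqv)])
  s2 <- strand_sites(comp, chain_ids[2])
  off <- nrow(s1$particles)
  particles <- rbind(s1$particles, s2$particles)
  s2$S <- s2$S + off; s2$B <- s2$B + off; s2$P <- s2$P + off

  qb <- function(i, j, b0key) data.frame(i = i, j = j, style = "quartic",
    k = NA_real_, k2 = dn$bond$k2, k4 = dn$bond$k4,
    b0 = unname(dn$bond$b0[b0key]), stringsAsFactors = FALSE)
  ha <- function(i, j, k, key) data.frame(i = i, j = j, k = k,
    style = "harmonic", table = NA_character_, eps = NA_real_,
    r0 = NA_real_, w = NA_real_, ka = dn$angle$ka,
    theta0 = unname(dn$angle$theta0[key]), stringsAsFactors = FALSE)

  bonds <- .empty_bonds(); angles <- .empty_angles()
  dihedrals <- .empty_dihedrals()
  stack <- pairt <- crosst <- NULL
  for (st in list(s1, s2)) {
    S <- st$S; B <- st$B; P <- st$P
    bonds <- rbind(bonds, qb(S, B, "SB"))
    if (n > 1) {
      t2 <- 2:n
      bonds <- rbind(bonds, qb(S[t2 - 1], P[t2], "SP"), qb(P[t2], S[t2], "PS"))
      angles <- rbind(angles,
        ha(S[t2 - 1], P[t2], S[t2], "SPS"),
        ha(B[t2 - 1], S[t2 - 1], P[t2], "BSP"),
        ha(P[t2], S[t2], B[t2], "PSB"))
      if (n > 2) {
        t3 <- 2:(n - 1)
        angles <- rbind(angles, ha(P[t3], S[t3], P[t3 + 1], "PSP"))
      }
      # backbone dihedrals S-P-S-P / P-S-P-S where defined
      if (n > 2) {
        t3 <- 2:(n - 1)
        dg <- dn$dihedral$gaussian; dp <- dn$dihedral$periodic
        mk <- function(i, j, k, l) rbind(
          data.frame(i = i, j = j, k = k, l = l, style = "periodic",
                     table = NA_character_, eps = NA_real_, phi0 = dp$phi0,
                     sigma = NA_real_, kp = dp$k, n = dp$n,
                     stringsAsFactors = FALSE),
          data.frame(i = i, j = j, k = k, l = l, style = "gaussian",
                     table = NA_character_, eps = dg$eps, phi0 = dg$phi0,
                     sigma = dg$sigma0, kp = NA_real_, n = NA_real_,
                     stringsAsFactors = FALSE))
        dihedrals <- rbind(dihedrals,
          mk(S[t3 - 1], P[t3], S[t3], P[t3 + 1]),
          mk(P[t3], S[t3], P[t3 + 1], S[t3 + 1]))
      }
      # intra-strand stacking between consecutive bases
      stk <- dn$stack
      stack <- rbind(stack, data.frame(
        s1 = S[1:(n - 1)], b1 = B[1:(n - 1)], b2 = B[2:n],
        eps = stk$eps, alpha = stk$alpha, r0 = stk$r0,
        theta0 = stk$theta0, gamma = stk$gamma))
    }
  }
  # Watson-Crick pairs: strand-1 base t pairs strand-2 base (n + 1 - t)
  pr <- dn$pair; cs <- dn$cross
  partner <- n + 1 - seq_len(n)
  pairt <- data.frame(
    s1 = s1$S, b1 = s1$B, b2 = s2$B[partner], s2 = s2$S[partner],
    eps = pr$eps, alpha = pr$alpha, r0 = pr$r0,
    theta1_0 = pr$theta1_0, theta2_0 = pr$theta2_0, phi0 = pr$phi0,
    gamma = pr$gamma)
  # cross-stacking with the partner's neighbors
  t_up <- which(partner + 1 <= n); t_dn <- which(partner - 1 >= 1)
  crosst <- rbind(
    if (length(t_up)) data.frame(
      s1 = s1$S[t_up], b1 = s1$B[t_up],
      b2 = s2$B[partner[t_up] + 1], s2 = s2$S[partner[t_up] + 1],
      eps = cs$eps, alpha = cs$alpha, r0 = cs$r0,
      theta3_0 = cs$theta3_0, thetaCS_0 = cs$thetaCS_0, gamma = cs$gamma),
    if (length(t_dn)) data.frame(
      s1 = s1$S[t_dn], b1 = s1$B[t_dn],
      b2 = s2$B[partner[t_dn] - 1], s2 = s2$S[partner[t_dn] - 1],
      eps = cs$eps, alpha = cs$alpha, r0 = cs$r0,
      theta3_0 = cs$theta3_0, thetaCS_0 = cs$thetaCS_0, gamma = cs$gamma))
  cg_topology(particles, bonds, angles, dihedrals,
              dna_stack = stack, dna_pair = pairt, dna_cross = crosst)
}

#' Replicate a system
#'
#' Concatenates `n_copies` of a topology, renumbering chain ids and
#' re-indexing every term list; no bonded terms are created between
#' copies. When coordinates and rigid placements are supplied, each copy
#' is transformed by its placement.
#'
#' @param topology a `cg_topology`.
#' @param n_copies number of copies.
#' @param placements optional list (length `n_copies`) of
#'   `list(R = 3x3 rotation, t = translation)`; `R` must be proper
#'   (orthogonal, det +1).
#' @param coords optional coordinate matrix of the original system.
#' @param box optional box lengths; placements leaving the box trigger a
#'   warning (coordinates are kept; wrap at run time).
#' @return the replicated `cg_topology`, with a `coords` attribute when
#'   coordinates were supplied.
#' @export
replicate_system <- function(topology, n_copies, placements = NULL,
                             coords = NULL, box = NULL) {
  stopifnot(n_copies >= 1)
  if (!is.null(placements)) {
    if (length(placements) != n_copies)
      stop("need exactly one placement per copy")
    for (pl in placements) {
      R <- pl$R
      if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
        stop("placement rotation is not a proper rigid motion")
    }
  }
  np <- nrow(topology$particles)
  nch <- length(unique(topology$particles$chain_id))
  chain_map <- match(topology$particles$chain_id,
                     sort(unique(topology$particles$chain_id)))
  copy_idx <- rep(seq_len(n_copies), each = np)
  pt <- topology$particles[rep(seq_len(np), n_copies), , drop = FALSE]
  pt$chain_id <- chain_map[rep(seq_len(np), n_copies)] +
    (copy_idx - 1L) * nch
  rownames(pt) <- NULL
  shift_df <- function(df, cols) {
    if (is.null(df) || nrow(df) == 0) return(df)
    nr <- nrow(df)
    out <- df[rep(seq_len(nr), n_copies), , drop = FALSE]
    offs <- rep((seq_len(n_copies) - 1L) * np, each = nr)
    for (cl in cols) out[[cl]] <- out[[cl]] + offs
    rownames(out) <- NULL
    out
  }
  new <- topology
  new$particles <- pt
  new$bonds <- .style_contiguous(shift_df(topology$bonds, c("i", "j")))
  new$angles <- .style_contiguous(shift_df(topology$angles,
                                           c("i", "j", "k")))
  new$dihedrals <- .style_contiguous(shift_df(topology$dihedrals,
                                              c("i", "j", "k", "l")))
  new$native_contacts <- shift_df(topology$native_contacts, c("i", "j"))
  new$dna_stack <- shift_df(topology$dna_stack, c("s1", "b1", "b2"))
  new$dna_pair <- shift_df(topology$dna_pair, c("s1", "b1", "b2", "s2"))
  new$dna_cross <- shift_df(topology$dna_cross, c("s1", "b1", "b2", "s2"))
  new$pwmcos_sites <- shift_df(topology$pwmcos_sites,
                               c("b", "s", "c", "cm", "cp"))
  validate_topology(new)
  if (!is.null(coords)) {
    stopifnot(nrow(coords) == np)
    allc <- matrix(0, np * n_copies, 3)
    for (cc in seq_len(n_copies)) {
      xc <- coords
      if (!is.null(placements)) {
        pl <- placements[[cc]]
        xc <- xc %*% t(pl$R)
        xc <- sweep(xc, 2, pl$t, "+")
      }
      allc[(cc - 1L) * np + seq_len(np), ] <- xc
    }
    if (!is.null(box) && (any(allc < 0) || any(sweep(allc, 2, box) > 0)))
      warning("placed coordinates extend beyond the box; they will be ",
              "wrapped at run time")
    attr(new, "coords") <- allc
  }
  new
}
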