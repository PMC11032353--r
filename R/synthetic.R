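## Seeded generators for every fixture the tests and demos need: packed
## droplets of self-avoiding chains, two-droplet fusion setups,
## multi-droplet boxes, and randomized but physically sane parameter
## tables. Direct geometric packing replaces slow compression
## equilibration; all outputs are deterministic for a fixed seed.

#' Generate one packed droplet of CG chains
#'
#' Chain centers of mass are uniform in a ball of the given radius;
#' each chain is grown as a self-avoiding random walk with fixed bond
#' length, and no two beads anywhere come closer than `min_sep`.
#'
#' @param n_chains number of chains.
#' @param chain_length beads per chain.
#' @param radius droplet radius (A) for the chain COMs.
#' @param seed RNG seed.
#' @param bond_length bond length (A), default 3.8.
#' @param min_sep global minimum bead separation (A), default 2.
#' @param center droplet center (length 3), default origin.
#' @return list with `coords` ((n_chains * chain_length) x 3) and
#'   `chains` (per-chain index list).
#' @export
gen_droplet <- function(n_chains, chain_length, radius, seed = 1L,
                        bond_length = 3.8, min_sep = 2,
                        center = c(0, 0, 0)) {
  stopifnot(n_chains >= 1, chain_length >= 1, radius > 0)
  # crude feasibility: bead hard-sphere volume vs inflated droplet volume
  reach <- radius + bond_length * sqrt(chain_length)
  occ <- n_chains * chain_length * (4 / 3) * pi * (min_sep / 2)^3
  avail <- 0.55 * (4 / 3) * pi * reach^3
  if (occ > avail) {
    r_lim <- ((occ / 0.55) / ((4 / 3) * pi))^(1 / 3)
    stop(sprintf(
      "packing infeasible: %d beads at %.1f A spacing need radius >= %.1f A",
      n_chains * chain_length, min_sep, r_lim))
  }
  set.seed(seed)
  placed <- matrix(numeric(0), 0, 3)
  chains <- vector("list", n_chains)
  unit_sphere <- function(n) {
    v <- matrix(stats::rnorm(3 * n), n, 3)
    v / row_norm(v)
  }
  for (ch in seq_len(n_chains)) {
    ok <- FALSE
    for (attempt in 1:2000) {
      # COM target uniform in the ball
      repeat {
        p <- stats::runif(3, -radius, radius)
        if (sum(p * p) <= radius^2) break
      }
      # grow the walk from the origin, then recenter its COM onto p
      w <- matrix(0, chain_length, 3)
      good <- TRUE
      if (chain_length > 1) {
        for (b in 2:chain_length) {
          placed_step <- FALSE
          for (try_dir in 1:100) {
            cand <- w[b - 1, ] + bond_length * unit_sphere(1)[1, ]
            if (b > 2) {
              d2 <- rowSums((w[1:(b - 2), , drop = FALSE] -
                               matrix(cand, b - 2, 3, byrow = TRUE))^2)
              if (min(d2) < min_sep^2) next
            }
            w[b, ] <- cand
            placed_step <- TRUE
            break
          }
          if (!placed_step) { good <- FALSE; break }
        }
      }
      if (!good) next
      w <- w - matrix(colMeans(w), chain_length, 3, byrow = TRUE) +
        matrix(p, chain_length, 3, byrow = TRUE)
      if (nrow(placed) > 0) {
        clash <- FALSE
        for (b in seq_len(chain_length)) {
          d2 <- rowSums((placed - matrix(w[b, ], nrow(placed), 3,
                                         byrow = TRUE))^2)
          if (min(d2) < min_sep^2) { clash <- TRUE; break }
        }
        if (clash) next
      }
      chains[[ch]] <- nrow(placed) + seq_len(chain_length)
      placed <- rbind(placed, w)
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf(
        "could not place chain %d of %d: radius %.1f A is the limiting size",
        ch, n_chains, radius))
  }
  placed <- placed + matrix(center, nrow(placed), 3, byrow = TRUE)
  list(coords = placed, chains = chains)
}

#' Generate a two-droplet fusion setup
#'
#' Two droplets placed along z with a given surface gap, labeled 1 and 2
#' by droplet of origin (the initial populations of the mixing
#' coordinate).
#'
#' @param n_chains_per chains per droplet.
#' @param chain_length beads per chain.
#' @param radius droplet radius (A).
#' @param gap surface-to-surface gap along z (A); must be > 0.
#' @param box box lengths (A).
#' @param seed RNG seed.
#' @return list with `coords`, `chains`, `labels` (1/2 per chain),
#'   `centers` (2 x 3).
#' @export
gen_two_droplet_system <- function(n_chains_per, chain_length, radius,
                                   gap = 20, box = NULL, seed = 1L, ...) {
  if (gap <= 0) stop("droplets overlap: surface gap must be > 0")
  if (is.null(box))
    box <- c(6 * radius, 6 * radius, 2 * (2 * radius + gap) + 4 * radius)
  half_sep <- radius + gap / 2
  c1 <- c(box[1] / 2, box[2] / 2, box[3] / 2 - half_sep)
  c2 <- c(box[1] / 2, box[2] / 2, box[3] / 2 + half_sep)
  if (c1[3] - radius < 0 || c2[3] + radius > box[3])
    stop("droplets do not fit the box along z")
  d1 <- gen_droplet(n_chains_per, chain_length, radius, seed = seed,
                    center = c1, ...)
  d2 <- gen_droplet(n_chains_per, chain_length, radius, seed = seed + 1L,
                    center = c2, ...)
  coords <- rbind(d1$coords, d2$coords)
  off <- nrow(d1$coords)
  chains <- c(d1$chains, lapply(d2$chains, function(v) v + off))
  list(coords = coords, chains = chains,
       labels = rep(c(1L, 2L), each = n_chains_per),
       centers = rbind(c1, c2), box = box)
}

#' Generate a multi-droplet box
#'
#' Non-overlapping droplet centers are placed by rejection sampling
#' (periodic minimum-image separation), radii uniform in the given
#' range, and each droplet is filled by [gen_droplet()] at the target
#' chain density.
#'
#' @param n_droplets droplet count.
#' @param radius_range length-2 range of droplet radii (A).
#' @param box box lengths (A).
#' @param seed RNG seed.
#' @param chain_length beads per chain.
#' @param density chains per A^3 inside a droplet (default 2e-4).
#' @param max_attempts placement attempts per droplet before rejection.
#' @param min_gap minimum surface-to-surface separation between droplets
#'   (A); 0 allows touching spheres.
#' @return list with `coords`, `chains`, `droplet_of` (droplet id per
#'   chain), `centers`, `radii`.
#' @export
gen_multi_droplet_system <- function(n_droplets, radius_range = c(50, 200),
                                     box, seed = 1L, chain_length = 10,
                                     density = 2e-4, max_attempts = 1000,
                                     min_gap = 0, ...) {
  set.seed(seed)
  radii <- stats::runif(n_droplets, radius_range[1], radius_range[2])
  if (sum((4 / 3) * pi * radii^3) > 0.3 * prod(box))
    stop("droplet volume fraction exceeds 0.3: enlarge the box")
  centers <- matrix(NA_real_, n_droplets, 3)
  for (d in seq_len(n_droplets)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      cand <- stats::runif(3) * box
      if (d > 1) {
        prev <- centers[seq_len(d - 1), , drop = FALSE]
        dd <- min_image(prev - matrix(cand, d - 1, 3, byrow = TRUE), box)
        if (any(row_norm(dd) < radii[seq_len(d - 1)] + radii[d] + min_gap))
          next
      }
      centers[d, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place droplet ", d, " after ", max_attempts,
           " attempts")
  }
  coords <- NULL; chains <- list(); droplet_of <- integer(0)
  for (d in seq_len(n_droplets)) {
    n_ch <- max(2L, round(density * (4 / 3) * pi * radii[d]^3))
    dr <- gen_droplet(n_ch, chain_length, radii[d], seed = seed + d,
                      center = centers[d, ], ...)
    off <- if (is.null(coords)) 0L else nrow(coords)
    coords <- rbind(coords, dr$coords)
    chains <- c(chains, lapply(dr$chains, function(v) v + off))
    droplet_of <- c(droplet_of, rep(d, n_ch))
  }
  list(coords = coords, chains = chains, droplet_of = droplet_of,
       centers = centers, radii = radii, box = box)
}

#' Generate a randomized but physically sane parameter set
#'
#' Per-residue diameters uniform in [4, 7] A and hydropathies uniform in
#' [0, 1]; smooth strictly positive normalized flexible angle/dihedral
#' tables; the published model constants (HPS well depth 0.2 kcal/mol,
#' bond force constant 2.39 kcal/mol/A^2, reference bond 3.8 A,
#' excluded-volume strength 0.6 kcal/mol) are kept fixed.
#'
#' @param residue_types residue codes to tabulate (default the 20 amino
#'   acids).
#' @param seed RNG seed.
#' @param n_grid flexible-table grid size.
#' @param ... passed to [cg_parameters()] (temperature, cutoffs, ...).
#' @return a `cg_parameters` object.
#' @export
gen_test_parameters <- function(residue_types = NULL, seed = 1L,
                                n_grid = 61L, ...) {
  set.seed(seed)
  base <- cg_parameters(...)
  res <- base$residues
  if (!is.null(residue_types))
    res <- res[res$code %in% residue_types, , drop = FALSE]
  res$sigma <- stats::runif(nrow(res), 4, 7)
  res$lambda <- stats::runif(nrow(res), 0, 1)
  p <- cg_parameters(residues = res, ...)
  smooth_table <- function(grid, periodic) {
    k <- 1:3
    a <- stats::rnorm(3, 0, 0.4); b <- stats::rnorm(3, 0, 0.4)
    span <- if (periodic) 2 * pi else diff(range(grid)) * 2
    lp <- sapply(grid, function(g)
      sum(a * cos(2 * pi * k * g / span) + b * sin(2 * pi * k * g / span)))
    pr <- exp(lp)
    h <- diff(grid[1:2])
    list(grid = grid, prob = pr / (sum(pr) * h))
  }
  ang_grid <- seq(0.02 * pi, 0.98 * pi, length.out = n_grid)
  dih_grid <- seq(-pi, pi - 2 * pi / n_grid, length.out = n_grid)
  for (code in res$code) {
    p$flexible$angle[[code]] <- smooth_table(ang_grid, periodic = FALSE)
    p$flexible$dihedral[[code]] <- smooth_table(dih_grid, periodic = TRUE)
  }
  validate_parameters(p)
  p
}
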