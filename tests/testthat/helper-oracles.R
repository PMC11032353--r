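# Shared fixtures and independent oracles for the test suite. Every
# oracle here is written as plainly as possible (double loops, closed
# forms) and stays independent of the implementation path it checks.

# minimum-image displacement for the oracles (scalar-style)
mi_vec <- function(d, box) d - box * round(d / box)

# brute-force O(N^2) pair scan with minimum image
brute_pairs <- function(x, box, rmax) {
  n <- nrow(x)
  out <- list(i = integer(0), j = integer(0), r = numeric(0))
  for (a in seq_len(max(0, n - 1))) {
    for (b in (a + 1):n) {
      d <- mi_vec(x[a, ] - x[b, ], box)
      r <- sqrt(sum(d^2))
      if (r < rmax) {
        out$i <- c(out$i, a); out$j <- c(out$j, b); out$r <- c(out$r, r)
      }
    }
  }
  out
}

pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = ":")

# central-difference gradient of a scalar function of one coordinate matrix
num_grad <- function(f, x, h = 1e-5, rows = seq_len(nrow(x))) {
  g <- matrix(NA_real_, nrow(x), 3)
  for (a in rows) {
    for (c in 1:3) {
      xp <- x; xp[a, c] <- xp[a, c] + h
      xm <- x; xm[a, c] <- xm[a, c] - h
      g[a, c] <- (f(xp) - f(xm)) / (2 * h)
    }
  }
  g
}

expect_force_matches_gradient <- function(force, grad, rows,
                                          tol_rel = 1e-5, tol_abs = 1e-8) {
  fa <- force[rows, , drop = FALSE]
  ga <- -grad[rows, , drop = FALSE]
  denom <- pmax(abs(ga), tol_abs / tol_rel)
  expect_lt(max(abs(fa - ga) / denom), tol_rel)
}

# a small random HPS-only multi-chain system in a box
toy_hps_system <- function(n_chains = 4, chain_length = 5, seed = 2,
                           box = c(90, 90, 90), temperature_K = 300,
                           cutoffs = c(exv = 10, dna = 12, hps = 20,
                                       ele = 20)) {
  params <- gen_test_parameters(seed = seed, temperature_K = temperature_K,
                                cutoffs = cutoffs)
  gen <- gen_droplet(n_chains, chain_length, radius = 16, seed = seed,
                     min_sep = 4.5)
  codes <- sample(params$residues$code, chain_length, replace = TRUE)
  top <- replicate_system(
    build_protein_topology(paste(codes, collapse = ""), params = params),
    n_chains)
  state <- cg_state(gen$coords + 30, box = box, seed = seed)
  list(params = params, topology = top, state = state, chains = gen$chains)
}

# conditions of the scaled-down two-droplet fusion demonstration
fusion_conditions <- function() {
  res_tab <- data.frame(code = "X", sigma = 6, lambda = 1, charge = 0,
                        mass = 100, stringsAsFactors = FALSE)
  params <- cg_parameters(temperature_K = 250, residues = res_tab,
                          cutoffs = c(exv = 10, dna = 12, hps = 20,
                                      ele = 20))
  list(params = params, n_chains_per = 20, chain_length = 10,
       radius = 24, gap = 10, box = c(150, 150, 220), min_sep = 5,
       steps = 2e5, dt = 10, friction_ps = 0.01)
}

run_fusion_demo <- function(seed, steps = NULL, out_stride = NULL) {
  fc <- fusion_conditions()
  if (is.null(steps)) steps <- fc$steps
  if (is.null(out_stride)) out_stride <- max(1L, steps %/% 40L)
  two <- gen_two_droplet_system(fc$n_chains_per, fc$chain_length,
                                fc$radius, fc$gap, fc$box,
                                seed = seed, min_sep = fc$min_sep)
  top <- replicate_system(
    build_protein_topology(paste(rep("X", fc$chain_length), collapse = ""),
                           params = fc$params),
    2 * fc$n_chains_per)
  st <- cg_state(two$coords, box = two$box, seed = seed)
  st$velocities <- maxwell_velocities(top$particles$mass,
                                      fc$params$environment$temperature_K,
                                      seed)
  res <- run_simulation(top, st, fc$params, steps = steps, dt = fc$dt,
                        friction_ps = fc$friction_ps,
                        out_stride = out_stride, keep_frames = TRUE)
  m <- vapply(res$frames, function(fr)
    mixing_metrics(fr, two$chains, two$labels, two$box)$m, numeric(1))
  list(run = res, system = two, m = m)
}

# independent DBSCAN oracle: connected components of the core-point
# graph (igraph), borders attached to an adjacent core component
dbscan_oracle <- function(adj, min_pts, min_cluster_size) {
  n <- nrow(adj)
  diag(adj) <- TRUE
  core <- rowSums(adj) >= min_pts
  labels <- rep(0L, n)
  if (any(core)) {
    sub <- adj[core, core, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub != 0, mode = "undirected")
    comp <- igraph::components(g)$membership
    labels[core] <- comp
    for (p in which(!core)) {
      nb <- which(adj[p, ] & core)
      if (length(nb)) labels[p] <- labels[nb[1]]
    }
  }
  sizes <- tabulate(labels, nbins = max(labels, 1))
  keep <- which(sizes >= min_cluster_size)
  remap <- integer(max(labels, 1)); remap[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  labels
}

# identical partitions up to label permutation
same_partition <- function(a, b) {
  if (any((a == 0) != (b == 0))) return(FALSE)
  ok <- TRUE
  for (lb in setdiff(unique(a), 0)) {
    members <- which(a == lb)
    ok <- ok && length(unique(b[members])) == 1 &&
      all(which(b == b[members[1]]) == members)
  }
  ok
}
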