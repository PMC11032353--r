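# Whole-system energies and forces: brute-force double-loop oracles,
# finite-difference gradients, Newton's third law, rigid-motion
# invariance and kind-based class assignment.

two_bead_system <- function(kinds, codes, r, params, charges = c(0, 0)) {
  parts <- data.frame(chain_id = 1:2, residue_index = 1:2, kind = kinds,
                      code = codes, charge = charges, mass = 100,
                      stringsAsFactors = FALSE)
  top <- cg_topology(parts)
  st <- cg_state(rbind(c(50, 50, 50), c(50 + r, 50, 50)),
                 box = c(100, 100, 100))
  grid <- build_cell_grid(st, params$cutoffs$ele + params$buffer)
  nb <- build_neighbor_lists(st, grid, params, top)
  list(top = top, st = st, nb = nb)
}

test_that("pair-class assignment by particle kind matches the scalar terms", {
  params <- gen_test_parameters(seed = 31, cutoffs = c(exv = 14, dna = 16,
                                                       hps = 20, ele = 20))
  rt <- params$residues
  sig <- function(c1, c2) mean(rt$sigma[match(c(c1, c2), rt$code)])
  lam <- function(c1, c2) mean(rt$lambda[match(c(c1, c2), rt$code)])
  r <- 7.3
  # disordered-disordered -> HPS only
  s1 <- two_bead_system(rep("disordered_protein", 2), c("A", "W"), r, params)
  e1 <- total_energy_forces(s1$top, s1$st, params, s1$nb)$energies
  expect_equal(unname(e1["hps"]),
               hps_pair_energy(r, sig("A", "W"), lam("A", "W"))$energy)
  expect_equal(unname(e1["exv"]), 0)
  # ordered-ordered (non-native) -> structure-based excluded volume only
  s2 <- two_bead_system(rep("ordered_protein", 2), c("A", "W"), r, params)
  e2 <- total_energy_forces(s2$top, s2$st, params, s2$nb)$energies
  expect_equal(unname(e2["exv"]),
               excluded_volume_energy(r, "aicg",
                 list(eps = params$aicg$eps_exv,
                      sigma = sig("A", "W")))$energy)
  expect_equal(unname(e2["hps"]), 0)
  # charged pair adds the screened electrostatic term
  s3 <- two_bead_system(rep("disordered_protein", 2), c("K", "E"), r,
                        params, charges = c(1, -1))
  e3 <- total_energy_forces(s3$top, s3$st, params, s3$nb)$energies
  Tk <- params$environment$temperature_K
  epsr <- relative_permittivity(Tk, params$environment$salt_molarity)
  lamd <- debye_length(Tk, params$environment$ionic_strength, epsr)
  expect_equal(unname(e3["ele"]),
               debye_huckel_energy(r, 1, -1, epsr, lamd)$energy)
  # beyond every cutoff -> zero energies, zero forces
  s4 <- two_bead_system(rep("disordered_protein", 2), c("A", "W"), 30,
                        params)
  r4 <- total_energy_forces(s4$top, s4$st, params, s4$nb)
  expect_true(all(r4$energies == 0))
  expect_true(all(r4$forces == 0))
})

test_that("random HPS system equals the brute-force double loop", {
  sys <- toy_hps_system(n_chains = 4, chain_length = 5, seed = 33)
  grid <- build_cell_grid(sys$state, sys$params$cutoffs$ele +
                            sys$params$buffer)
  nb <- build_neighbor_lists(sys$state, grid, sys$params, sys$topology)
  got <- total_energy_forces(sys$topology, sys$state, sys$params, nb)
  # oracle: plain loops over all pairs with bonded/1-3 exclusions
  x <- sys$state$coords; box <- sys$state$box
  rt <- sys$params$residues
  codes <- sys$topology$particles$code
  chain <- sys$topology$particles$chain_id
  resn <- ave(seq_along(chain), chain, FUN = seq_along)
  e_hps <- 0
  n <- nrow(x)
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    if (chain[a] == chain[b] && abs(resn[a] - resn[b]) <= 2) next
    d <- mi_vec(x[a, ] - x[b, ], box)
    r <- sqrt(sum(d^2))
    if (r >= sys$params$cutoffs$hps) next
    sg <- mean(rt$sigma[match(c(codes[a], codes[b]), rt$code)])
    lm <- mean(rt$lambda[match(c(codes[a], codes[b]), rt$code)])
    s6 <- (sg / r)^6
    elj <- 4 * 0.2 * (s6^2 - s6)
    e_hps <- e_hps + if (r <= 2^(1 / 6) * sg) elj + (1 - lm) * 0.2
    else lm * elj
  }
  expect_equal(unname(got$energies["hps"]), e_hps, tolerance = 1e-10)
  # bond energy oracle
  bds <- sys$topology$bonds
  e_b <- 0
  for (q in seq_len(nrow(bds))) {
    d <- mi_vec(x[bds$i[q], ] - x[bds$j[q], ], box)
    e_b <- e_b + bds$k[q] * (sqrt(sum(d^2)) - bds$b0[q])^2
  }
  expect_equal(unname(got$energies["bond"]), e_b, tolerance = 1e-10)
})

test_that("forces equal minus the numeric gradient for a mixed system", {
  params <- gen_test_parameters(seed = 35, cutoffs = c(exv = 10, dna = 14,
                                                       hps = 18, ele = 20))
  prot <- build_protein_topology("ADKLMG", list(
    list(range = c(1, 6), model = "AICG2+")), params)
  prot <- set_native_contacts(prot, data.frame(i = 1, j = 5, sigma = 8,
                                               eps = 0.4))
  dna <- build_dsdna_topology("ACG", params)
  both <- replicate_system(prot, 1)
  # merge protein + DNA by hand
  off <- n_particles(prot)
  merged <- prot
  merged$particles <- rbind(prot$particles, dna$particles)
  shift <- function(df, cols) {
    if (is.null(df) || nrow(df) == 0) return(df)
    for (cl in cols) df[[cl]] <- df[[cl]] + off
    df
  }
  merged$bonds <- rbind(prot$bonds, shift(dna$bonds, c("i", "j")))
  merged$angles <- rbind(prot$angles, shift(dna$angles, c("i", "j", "k")))
  merged$angles <- merged$angles[order(match(merged$angles$style,
                                             unique(merged$angles$style))), ]
  merged$dihedrals <- rbind(prot$dihedrals,
                            shift(dna$dihedrals, c("i", "j", "k", "l")))
  merged$dihedrals <- merged$dihedrals[
    order(match(merged$dihedrals$style, unique(merged$dihedrals$style))), ]
  merged$dna_stack <- shift(dna$dna_stack, c("s1", "b1", "b2"))
  merged$dna_pair <- shift(dna$dna_pair, c("s1", "b1", "b2", "s2"))
  merged$dna_cross <- shift(dna$dna_cross, c("s1", "b1", "b2", "s2"))
  merged <- validate_topology(merged)
  # plausible, non-degenerate coordinates
  set.seed(36)
  n <- n_particles(merged)
  x <- matrix(0, n, 3)
  x[1:6, ] <- cbind(seq(0, by = 3.8, length.out = 6), 0, 0) +
    matrix(rnorm(18, 0, 0.4), 6, 3)
  helix <- function(tvals, phase, radius = 5)
    cbind(radius * cos(tvals + phase), radius * sin(tvals + phase),
          3.3 * tvals)
  x[7:14, ] <- (helix(rep(1:3, each = 3), 0) +
                  matrix(rnorm(27, 0, 0.3), 9, 3))[1:8, ]
  x[7:14, 1] <- x[7:14, 1] + 14
  x[15:22, ] <- (helix(rep(1:3, each = 3), pi) +
                   matrix(rnorm(27, 0, 0.3), 9, 3))[1:8, ]
  x[15:22, 1] <- x[15:22, 1] + 14
  x <- x + 40
  st <- cg_state(x, box = c(100, 100, 100))
  grid <- build_cell_grid(st, params$cutoffs$ele + params$buffer)
  nb <- build_neighbor_lists(st, grid, params, merged)
  got <- suppressWarnings(total_energy_forces(merged, st, params, nb))
  expect_true(all(is.finite(got$forces)))
  etot <- function(xx) {
    st2 <- st; st2$coords <- xx
    sum(suppressWarnings(total_energy_forces(merged, st2, params, nb,
                                             check_stale = FALSE))$energies)
  }
  rows <- c(1, 3, 6, 7, 9, 12, 15, 20, 22)
  g <- num_grad(etot, x, rows = rows)
  expect_force_matches_gradient(got$forces, g, rows, tol_rel = 2e-5)
  # Newton's third law over the whole system
  expect_lt(max(abs(colSums(got$forces))), 1e-8)
})

test_that("energies are invariant under rigid motion of the system", {
  sys <- toy_hps_system(n_chains = 3, chain_length = 5, seed = 37)
  grid <- build_cell_grid(sys$state, sys$params$cutoffs$ele +
                            sys$params$buffer)
  nb <- build_neighbor_lists(sys$state, grid, sys$params, sys$topology)
  e0 <- total_energy_forces(sys$topology, sys$state, sys$params, nb)$energies
  # translation (with wrap-around)
  st_t <- sys$state
  st_t$coords <- sweep(st_t$coords, 2, c(31.7, -12.3, 55.1), "+")
  grid_t <- build_cell_grid(st_t, sys$params$cutoffs$ele + sys$params$buffer)
  nb_t <- build_neighbor_lists(st_t, grid_t, sys$params, sys$topology)
  e_t <- total_energy_forces(sys$topology, st_t, sys$params, nb_t)$energies
  expect_equal(e_t, e0, tolerance = 1e-9)
  # rotation about the compact system's center
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  ctr <- colMeans(sys$state$coords)
  st_r <- sys$state
  st_r$coords <- sweep(sweep(sys$state$coords, 2, ctr) %*% t(R), 2, ctr,
                       "+")
  grid_r <- build_cell_grid(st_r, sys$params$cutoffs$ele + sys$params$buffer)
  nb_r <- build_neighbor_lists(st_r, grid_r, sys$params, sys$topology)
  e_r <- total_energy_forces(sys$topology, st_r, sys$params, nb_r)$energies
  expect_equal(e_r, e0, tolerance = 1e-9)
})

test_that("stale neighbor lists are rejected", {
  sys <- toy_hps_system(n_chains = 2, chain_length = 5, seed = 39)
  grid <- build_cell_grid(sys$state, sys$params$cutoffs$ele +
                            sys$params$buffer)
  nb <- build_neighbor_lists(sys$state, grid, sys$params, sys$topology)
  st2 <- sys$state
  st2$coords[1, ] <- st2$coords[1, ] + c(5, 0, 0)
  expect_error(total_energy_forces(sys$topology, st2, sys$params, nb),
               "stale")
})
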