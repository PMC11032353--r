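# Cell-based kd-tree decomposition: cover/disjointness, the exhaustive
# bisection oracle, halo coverage, midpoint pair ownership (decomposed
# energy = serial energy), and rebalancing.

fake_grid <- function(dims, edge = 10) {
  structure(list(ncell = as.integer(dims), edge = rep(edge, 3),
                 box = dims * edge), class = "cg_cell_grid")
}

# exhaustive min-max over all recursive axis-aligned bisections
oracle_best_load <- function(counts3d, n) {
  memo <- new.env(parent = emptyenv())
  best <- function(lo, hi, n) {
    key <- paste(c(lo, hi, n), collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (n == 1) {
      sum(counts3d[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
    } else {
      nl <- ceiling(n / 2); nr <- n - nl
      ext <- hi - lo + 1
      out <- Inf
      for (ax in 1:3) {
        if (ext[ax] < 2) next
        for (cpos in lo[ax]:(hi[ax] - 1)) {
          other <- prod(ext[-ax])
          if ((cpos - lo[ax] + 1) * other < nl ||
                (hi[ax] - cpos) * other < nr) next
          hl <- hi; hl[ax] <- cpos; lr <- lo; lr[ax] <- cpos + 1
          out <- min(out, max(best(lo, hl, nl), best(lr, hi, nr)))
        }
      }
      out
    }
    memo[[key]] <- v
    v
  }
  best(c(1, 1, 1), dim(counts3d), n)
}

test_that("partition covers the grid disjointly and handles edge cases", {
  grid <- fake_grid(c(4, 4, 4))
  part <- kdtree_partition(grid, rep(3, 64), 64)
  expect_equal(part$imbalance, 1)
  expect_true(all(vapply(part$cells, length, integer(1)) == 1))
  expect_equal(sort(unlist(part$cells, use.names = FALSE)), 1:64)
  # all particles in one cell, 2 subdomains: the heavy cell lands whole
  # in one subdomain which then carries all the weight
  counts <- rep(0, 64); counts[23] <- 500
  p2 <- kdtree_partition(grid, counts, 2)
  expect_equal(sort(unlist(p2$cells, use.names = FALSE)), 1:64)
  expect_equal(unname(sort(p2$counts)), c(0, 500))
  expect_true(all(vapply(p2$cells, length, integer(1)) > 0))
  expect_error(kdtree_partition(grid, rep(1, 64), 65), "exceeds")
  # determinism
  set.seed(9)
  cnt <- rpois(64, 10)
  a <- kdtree_partition(grid, cnt, 8)
  b <- kdtree_partition(grid, cnt, 8)
  expect_identical(a$assign, b$assign)
})

test_that("partition reaches the exhaustive bisection oracle's best load", {
  for (seed in c(5, 6, 7)) {
    set.seed(seed)
    dims <- c(6, 4, 4)
    counts <- rpois(prod(dims), 20)
    part <- kdtree_partition(fake_grid(dims), counts, 8)
    opt <- oracle_best_load(array(counts, dims), 8)
    expect_equal(max(part$counts), opt)
  }
  # non-power-of-two subdomain counts still partition validly
  set.seed(8)
  counts <- rpois(96, 15)
  p3 <- kdtree_partition(fake_grid(c(6, 4, 4)), counts, 5)
  expect_equal(sort(unlist(p3$cells, use.names = FALSE)), 1:96)
  expect_equal(sum(p3$counts), sum(counts))
})

test_that("cell-granularity balance bound holds on random instances", {
  for (seed in 11:13) {
    set.seed(seed)
    dims <- c(4, 4, 4)
    counts <- rpois(64, 8)
    n <- 8
    part <- kdtree_partition(fake_grid(dims), counts, n)
    bound <- 1 + max(counts) * n / sum(counts)
    expect_lte(part$imbalance, bound)
  }
})

test_that("halo plans are symmetric and cover the boundary layers", {
  grid <- fake_grid(c(4, 4, 4))
  part1 <- kdtree_partition(grid, rep(1, 64), 1)
  h1 <- halo_plan(part1, grid, shells = 1)
  expect_equal(length(h1$receive[[1]]), 0)
  # 2 subdomains split along one axis, 1 shell: halo = boundary layers
  part2 <- kdtree_partition(grid, rep(1, 64), 2)
  h2 <- halo_plan(part2, grid, shells = 1)
  # brute-force adjacency oracle: foreign cells Chebyshev-within 1
  xyz <- cgdroplet:::.cell_xyz(1:64, c(4L, 4L, 4L))
  cheb <- function(a, b, nc) {
    d <- abs(xyz[a, ] - xyz[b, ])
    d <- pmin(d, nc - d)
    max(d)
  }
  for (A in 1:2) {
    got <- sort(unlist(h2$receive[[A]], use.names = FALSE))
    own <- part2$cells[[A]]
    want <- sort(Filter(function(cell) {
      part2$assign[cell] != A &&
        any(vapply(own, function(o) cheb(cell, o, c(4, 4, 4)) <= 1,
                   logical(1)))
    }, 1:64))
    expect_equal(got, want)
  }
  # symmetry: what A receives from B is what B sends to A
  for (A in seq_along(h2$receive)) {
    for (B in names(h2$receive[[A]])) {
      expect_identical(h2$receive[[A]][[B]],
                       h2$send[[as.integer(B)]][[as.character(A)]])
    }
  }
})

test_that("2-shell halo covers every electrostatic-range pair", {
  sys <- toy_hps_system(n_chains = 6, chain_length = 5, seed = 41,
                        box = c(96, 96, 96))
  rp_ele <- sys$params$cutoffs$ele + sys$params$buffer
  grid <- build_cell_grid(sys$state, rp_ele)
  counts <- vapply(grid$members, length, integer(1))
  part <- kdtree_partition(grid, counts, 4)
  hp <- halo_plan(part, grid, shells = 2)
  pairs <- brute_pairs(sys$state$coords, sys$state$box, rp_ele)
  for (q in seq_along(pairs$i)) {
    ci <- grid$cell_of[pairs$i[q]]
    cj <- grid$cell_of[pairs$j[q]]
    owner <- assign_pair_owner(pairs$i[q], pairs$j[q], sys$state$coords,
                               grid, part)
    reach <- c(part$cells[[owner]],
               unlist(hp$receive[[owner]], use.names = FALSE))
    expect_true(all(c(ci, cj) %in% reach))
  }
})

test_that("midpoint ownership: decomposed energies sum to the serial total", {
  for (seed in c(51, 52)) {
    sys <- toy_hps_system(n_chains = 5, chain_length = 5, seed = seed,
                          box = c(96, 96, 96))
    rp_ele <- sys$params$cutoffs$ele + sys$params$buffer
    grid <- build_cell_grid(sys$state, rp_ele)
    counts <- vapply(grid$members, length, integer(1))
    nb <- build_neighbor_lists(sys$state, grid, sys$params, sys$topology)
    serial <- total_energy_forces(sys$topology, sys$state, sys$params, nb)
    e_serial <- unname(serial$energies["hps"])
    for (nsub in c(2, 4, 8)) {
      part <- kdtree_partition(grid, counts, nsub)
      ph <- nb$pairs$hps
      owner <- assign_pair_owner(ph$i, ph$j, sys$state$coords, grid, part)
      # per-subdomain energy over owned pairs only
      e_dec <- 0
      rt <- sys$params$residues
      codes <- sys$topology$particles$code
      for (sd in seq_len(nsub)) {
        sel <- which(owner == sd)
        if (!length(sel)) next
        d <- sys$state$coords[ph$i[sel], , drop = FALSE] -
          sys$state$coords[ph$j[sel], , drop = FALSE]
        d <- d - matrix(rep(sys$state$box, each = length(sel)),
                        ncol = 3) * round(d / matrix(rep(sys$state$box,
                          each = length(sel)), ncol = 3))
        r <- sqrt(rowSums(d^2))
        inside <- r < sys$params$cutoffs$hps
        if (!any(inside)) next
        sg <- (rt$sigma[match(codes[ph$i[sel]], rt$code)] +
                 rt$sigma[match(codes[ph$j[sel]], rt$code)]) / 2
        lm <- (rt$lambda[match(codes[ph$i[sel]], rt$code)] +
                 rt$lambda[match(codes[ph$j[sel]], rt$code)]) / 2
        e_dec <- e_dec + sum(hps_pair_energy(r[inside], sg[inside],
                                             lm[inside])$energy)
      }
      expect_equal(e_dec, e_serial, tolerance = 1e-10)
      # ownership is deterministic
      expect_identical(owner, assign_pair_owner(ph$i, ph$j,
                                                sys$state$coords, grid,
                                                part))
    }
  }
})

test_that("rebalancing: identity off-period, improvement on migration", {
  grid <- fake_grid(c(4, 4, 4))
  counts0 <- rep(2, 64)
  part <- kdtree_partition(grid, counts0, 8)
  # period Inf or off-period step: unchanged
  expect_identical(rebalance(part, grid, counts0, step = 10, period = Inf),
                   part)
  expect_identical(rebalance(part, grid, counts0, step = 7, period = 5),
                   part)
  # uniform -> uniform: imbalance stays perfect
  p2 <- rebalance(part, grid, counts0, step = 10, period = 5)
  expect_equal(p2$imbalance, 1)
  # migration: everything in one octant, then uniform
  xyz <- cgdroplet:::.cell_xyz(1:64, c(4L, 4L, 4L))
  octant <- which(xyz[, 1] < 2 & xyz[, 2] < 2 & xyz[, 3] < 2)
  counts_oct <- rep(0, 64); counts_oct[octant] <- 40
  part_oct <- kdtree_partition(grid, counts_oct, 8)
  expect_equal(part_oct$imbalance, 1)   # balanced for the octant load
  # particles spread out uniformly: old partition is now unbalanced
  counts_uni <- rep(5, 64)
  stale_counts <- vapply(part_oct$cells, function(idx) sum(counts_uni[idx]),
                         numeric(1))
  imb_before <- partition_imbalance(stale_counts)
  part_new <- rebalance(part_oct, grid, counts_uni, step = 100, period = 100)
  expect_lt(part_new$imbalance, imb_before)
  expect_equal(part_new$imbalance, 1)
})
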