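# Topology builders: particle/bond/angle counts, region handling, DNA
# site layout, native-contact extraction vs a brute-force scan, and
# replication re-indexing.

test_that("mixed-model protein chain reproduces the reference layout", {
  p <- cg_parameters()
  seqv <- paste(sample(p$residues$code, 154, replace = TRUE), collapse = "")
  set.seed(1)
  top <- build_protein_topology(seqv, list(
    list(range = c(261, 319), model = "HPS"),
    list(range = c(320, 334), model = "AICG2+"),
    list(range = c(335, 414), model = "HPS")), p, first_residue = 261)
  expect_equal(n_particles(top), 154)
  expect_equal(nrow(top$bonds), 153)
  ord <- top$particles$residue_index[top$particles$kind == "ordered_protein"]
  expect_equal(range(ord), c(320, 334))
  expect_equal(length(ord), 15)
  # local terms only inside the ordered region: 13 triples, 12 quadruples
  expect_equal(sum(top$angles$style == "flexible"), 13)
  expect_equal(sum(top$angles$style == "gaussian_13"), 13)
  expect_equal(sum(top$dihedrals$style == "flexible"), 12)
  expect_equal(sum(top$dihedrals$style == "gaussian"), 12)
})

test_that("degenerate chains: single residue and pure-HPS term lists", {
  p <- cg_parameters()
  one <- build_protein_topology("G", params = p)
  expect_equal(n_particles(one), 1)
  expect_equal(nrow(one$bonds), 0)
  expect_equal(nrow(one$angles), 0)
  five <- build_protein_topology("GAGAG", params = p)
  expect_equal(nrow(five$bonds), 4)
  expect_equal(nrow(five$angles), 0)     # HPS carries bonds only
  expect_equal(nrow(five$dihedrals), 0)
  expect_equal(five$particles$charge, rep(0, 5))
  chg <- build_protein_topology("KRDEH", params = p)
  expect_equal(chg$particles$charge, c(1, 1, -1, -1, 0))
})

test_that("region validation: gaps, overlaps, unknown codes rejected", {
  p <- cg_parameters()
  expect_error(build_protein_topology("GGGG", list(
    list(range = c(1, 2), model = "HPS")), p), "gap")
  expect_error(build_protein_topology("GGGG", list(
    list(range = c(1, 3), model = "HPS"),
    list(range = c(3, 4), model = "AICG2+")), p), "overlap")
  expect_error(build_protein_topology("GZG", params = p), "unknown residue")
})

test_that("dsDNA particle counts follow the 3n-1 sites-per-strand rule", {
  p <- cg_parameters()
  set.seed(2)
  seq200 <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  dna <- build_dsdna_topology(seq200, p)
  expect_equal(n_particles(dna), 1198)
  expect_equal(sum(dna$particles$kind == "dna_phosphate"), 2 * 199)
  expect_equal(sum(dna$particles$charge == -1), 2 * 199)
  one <- build_dsdna_topology("A", p)
  expect_equal(n_particles(one), 4)  # S+B per strand, no phosphate
  two <- build_dsdna_topology("AT", p)
  expect_equal(n_particles(two), 10)
  expect_equal(sum(two$particles$charge != 0), 2)
  expect_error(build_dsdna_topology("AXT", p), "invalid base")
  # complementary strand sequence (read back along residue order)
  d <- build_dsdna_topology("ACGT", p)
  s2 <- d$particles[d$particles$chain_id == 2 & d$particles$kind ==
                      "dna_base", ]
  expect_equal(paste(s2$code, collapse = ""), "ACGT")  # reverse complement
  # every Watson-Crick pair joins complementary bases
  expect_equal(nrow(d$dna_pair), 4)
  b <- d$particles$code
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  expect_true(all(b[d$dna_pair$b2] == unname(comp[b[d$dna_pair$b1]])))
})

test_that("native-contact extraction equals the exhaustive heavy-atom scan", {
  set.seed(3)
  n_res <- 8
  atoms <- lapply(1:n_res, function(q) {
    center <- matrix(runif(3, 0, 14), 1)
    center[rep(1, 4), ] + matrix(rnorm(12, 0, 1.2), 4, 3)
  })
  ref <- reference_structure(1:n_res, atoms)
  got <- extract_native_contacts(ref, cutoff = 4.5, min_seq_sep = 3)
  # oracle: plain double loop over residues and heavy-atom pairs
  expected <- NULL
  for (a in 1:(n_res - 1)) for (b in (a + 1):n_res) {
    if (b - a < 3) next
    hit <- FALSE
    for (qa in 1:4) for (qb in 1:4) {
      if (sqrt(sum((atoms[[a]][qa, ] - atoms[[b]][qb, ])^2)) <= 4.5)
        hit <- TRUE
    }
    if (hit) expected <- rbind(expected, c(a, b))
  }
  if (is.null(expected)) {
    expect_equal(nrow(got), 0)
  } else {
    expect_equal(got[, c("i", "j")], as.data.frame(expected) |>
                   stats::setNames(c("i", "j")),
                 ignore_attr = TRUE)
    # sigma is the bead-bead distance
    for (q in seq_len(nrow(got))) {
      expect_equal(got$sigma[q],
                   sqrt(sum((ref$bead[got$i[q], ] - ref$bead[got$j[q], ])^2)))
    }
  }
  # explicit small cases
  close_atoms <- list(matrix(c(0, 0, 0), 1), matrix(c(10, 0, 0), 1),
                      matrix(c(20, 0, 0), 1), matrix(c(20, 3, 0), 1))
  ref2 <- reference_structure(1:4, close_atoms)
  got2 <- extract_native_contacts(ref2)
  expect_equal(nrow(got2), 0)  # only |i-j| >= 3 pair is 1-4 at 20.2 A
  close_atoms[[4]] <- matrix(c(3, 0, 0), 1)
  got3 <- extract_native_contacts(reference_structure(1:4, close_atoms))
  expect_equal(unlist(got3[, c("i", "j")], use.names = FALSE), c(1L, 4L))
  expect_error(reference_structure(1:2, list(matrix(c(0, 0, 0), 1), NULL)),
               "residue 2")
})

test_that("replication re-indexes all terms and preserves offsets", {
  p <- gen_test_parameters(seed = 5)
  top <- build_protein_topology("ADKLM", list(
    list(range = c(1, 5), model = "AICG2+")), p)
  rep3 <- replicate_system(top, 3)
  expect_equal(n_particles(rep3), 15)
  expect_equal(length(unique(rep3$particles$chain_id)), 3)
  # within-copy index differences are invariant
  np <- 5
  for (cc in 1:3) {
    sel <- rep3$bonds$i > (cc - 1) * np & rep3$bonds$i <= cc * np
    expect_equal(sort(rep3$bonds$j[sel] - rep3$bonds$i[sel]),
                 sort(top$bonds$j - top$bonds$i))
  }
  # no inter-copy bonded terms
  copy_of <- function(idx) (idx - 1) %/% np
  expect_true(all(copy_of(rep3$bonds$i) == copy_of(rep3$bonds$j)))
  expect_true(all(copy_of(rep3$angles$i) == copy_of(rep3$angles$k)))
  # identity replication
  rep1 <- replicate_system(top, 1)
  expect_equal(rep1$particles, top$particles, ignore_attr = TRUE)
  expect_equal(nrow(rep1$bonds), nrow(top$bonds))
})

test_that("headline particle counts reproduce under replication", {
  p <- cg_parameters()
  chain <- build_protein_topology(paste(rep("G", 154), collapse = ""),
                                  params = p)
  expect_equal(n_particles(replicate_system(chain, 1949)), 300146)
  expect_equal(n_particles(replicate_system(chain, 16657)), 2565178)
})

test_that("rigid placements transform coordinates, improper ones rejected", {
  p <- cg_parameters()
  top <- build_protein_topology("GAG", params = p)
  coords <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  th <- pi / 3
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  pl <- list(list(R = diag(3), t = c(0, 0, 0)),
             list(R = R, t = c(10, 0, 0)))
  rep2 <- replicate_system(top, 2, placements = pl, coords = coords)
  xc <- attr(rep2, "coords")
  expect_equal(xc[1:3, ], coords)
  expect_equal(xc[4:6, ], sweep(coords %*% t(R), 2, c(10, 0, 0), "+"))
  bad <- list(list(R = diag(c(1, 1, -1)), t = c(0, 0, 0)))
  expect_error(replicate_system(top, 1, placements = bad, coords = coords),
               "proper")
})

test_that("topology validation catches malformed term lists", {
  p <- cg_parameters()
  top <- build_protein_topology("GAGAG", params = p)
  bad <- top; bad$bonds$j[1] <- 99
  expect_error(validate_topology(bad), "out of range")
  bad2 <- top; bad2$bonds$j[1] <- bad2$bonds$i[1]
  expect_error(validate_topology(bad2), "distinct")
  bad3 <- top; bad3$bonds$style[1] <- "cubic"
  expect_error(validate_topology(bad3), "unknown style")
})
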