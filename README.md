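# cgdroplet

A desk-scale R engine for residue-level coarse-grained molecular
dynamics of biomolecular condensates. It targets the questions people
ask of liquid-liquid phase separation simulations — do two droplets
fuse, how do their contents mix, how does the condensate's shape relax,
how do droplet counts and sizes evolve — with the model stack used for
such systems at residue resolution:

* **HPS model** for intrinsically disordered proteins: one bead per
  residue, hydropathy-scaled Lennard-Jones pairs
  `E = E_LJ + (1-λ)ε` for `r ≤ 2^(1/6)σ`, `λ E_LJ` beyond
  (ε = 0.2 kcal/mol), harmonic bonds `k_b (b-b0)²` with
  k_b = 2.39 kcal/mol/Å², b0 = 3.8 Å.
* **Structure-based (Gō) model** for folded domains: native contacts
  `ε[5(σ/r)¹² − 6(σ/r)¹⁰]` extracted at a 4.5 Å heavy-atom cutoff,
  statistical flexible angle/dihedral potentials, shifted repulsive
  excluded volume.
* **Three-site DNA model**: quartic bonds, Morse-based stacking,
  Watson-Crick pairing and cross-stacking with angular modulation,
  phosphate charges.
* **Debye-Hückel electrostatics** with the empirical solution
  permittivity ε_r = e(T)·a(C) and screening length
  λ_D = sqrt(kB T ε0 ε_r / (2 N_A e² I)).
* **PWM-based protein-DNA recognition**: Gaussian wells modulated by
  three angles, with the complementary-base partner term.

Around the force field: a unified multi-cutoff Verlet neighbor list
(one sweep feeds the excluded-volume / DNA / HPS class lists, a
charged-only electrostatic list, and a buffer skin that skips rebuilds
until any particle moves half the skin), a cell-based kd-tree domain
decomposition with midpoint pair ownership and periodic load
rebalancing (verified in-process against serial energies), BAOAB
Langevin dynamics with counter-based noise (bit-reproducible and
schedule-independent), chain-level DBSCAN droplet clustering, the
mixing coordinate m = sqrt(D11·D22)/D12 and shape coordinate η, and
seeded generators for packed droplet systems.

The methods vignette (`vignettes/droplet-dynamics.Rmd`) documents the
equations, unit system, parameter defaults, design decisions and
limitations.

## Worked example: two droplets fuse and mix

```r
library(cgdroplet)

# one bead type: sigma 6 A, full hydropathy, uncharged, 100 Da
res_tab <- data.frame(code = "X", sigma = 6, lambda = 1,
                      charge = 0, mass = 100)
params <- cg_parameters(temperature_K = 250, residues = res_tab,
                        cutoffs = c(exv = 10, dna = 12, hps = 20, ele = 20))

# two 20-chain droplets (10 beads/chain), 10 A apart along z
two <- gen_two_droplet_system(20, 10, radius = 24, gap = 10,
                              box = c(150, 150, 220), seed = 1,
                              min_sep = 5)
top <- replicate_system(
  build_protein_topology(strrep("X", 10), params = params), 40)

st <- cg_state(two$coords, box = two$box, seed = 1)
st$velocities <- maxwell_velocities(top$particles$mass, 250, seed = 1)

res <- run_simulation(top, st, params, steps = 50000, out_stride = 5000)

m <- sapply(res$frames, function(fr)
  mixing_metrics(fr, two$chains, two$labels, two$box)$m)
round(m, 3)
#>  [1] 0.452 0.521 0.744 0.823 0.912 0.931 0.914 0.934 0.955 0.958 1.009
```

The mixing coordinate starts near R/d ≈ 0.45 (two separate droplets)
and relaxes to ≈ 1 as the droplets merge and their chains
interdiffuse. Clustering the first frame resolves the two droplets,
and the shape coordinate shows the initial two-lobe anisotropy
relaxing toward a sphere (η = 3):

```r
M <- chain_distance_matrix(res$frames[[1]], two$chains, two$box,
                           "contact", contact_cutoff = 8)
cluster_chains(M, "contact", min_pts = 3, min_cluster_size = 5)
#> <cg_clusters> 2 droplet(s); sizes: 19, 18; 3 noise chains
round(c(shape_eta(res$frames[[1]], two$box),
        shape_eta(res$frames[[11]], two$box)), 3)
#> [1] 6.111 3.433
```

A thin command-line front end wrapping these functions ships at
`inst/scripts/cgdroplet` (subcommands `build`, `run`, `partition`,
`analyze`; TSV/XYZ/PDB/YAML input and output).

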