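Package: cgdroplet
Title: Residue-Level Coarse-Grained Molecular Dynamics for Biomolecular Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A desk-scale coarse-grained molecular dynamics engine for
    liquid-liquid phase separation of proteins and nucleic acids at residue
    resolution. Implements the HPS hydropathy-scale model for disordered
    proteins, a structure-based Go model with statistical flexible local
    potentials for folded domains, a three-site-per-nucleotide DNA model with
    Morse-based stacking and pairing, Debye-Hueckel screened electrostatics,
    and a position-weight-matrix protein-DNA recognition potential. Around
    the force field it provides a unified multi-cutoff Verlet neighbor-list
    scheme with buffer-based rebuild skipping, a cell-based kd-tree domain
    decomposition with midpoint pair ownership and dynamic load balancing,
    BAOAB Langevin dynamics, seeded droplet-system generators, and droplet
    analysis (chain-level DBSCAN clustering, mixing and shape coordinates,
    density profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
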