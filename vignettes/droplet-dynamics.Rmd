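---
title: "Residue-level coarse-grained dynamics of biomolecular condensates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residue-level coarse-grained dynamics of biomolecular condensates: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgdroplet)
```

# Scope

`cgdroplet` is a desk-scale engine for residue-level coarse-grained (CG)
molecular dynamics of systems that undergo liquid-liquid phase
separation: intrinsically disordered proteins (IDPs) forming droplets,
folded domains embedded in them, and double-stranded DNA. One CG bead
represents an amino-acid residue; nucleotides carry three sites
(phosphate, sugar, base). Solvent is implicit. The package covers the
full pipeline — topology construction, force evaluation, multi-cutoff
neighbor lists, a cell-based kd-tree domain decomposition with dynamic
load balancing, Langevin dynamics, droplet analysis, and seeded
synthetic-system generators — at sizes that run on one CPU in minutes.
The decomposition is executed in-process: partitions, halo plans and
midpoint pair ownership are computed and verified against serial
results, standing in for actual message passing.

# The force field

## Disordered protein: hydropathy-scale (HPS) model

Bonded neighbors interact through a harmonic bond
$E_b = k_b (b - b_0)^2$ with $k_b = 2.39$ kcal/mol/Å² and $b_0 = 3.8$ Å.
Non-bonded residue pairs use the Ashbaugh–Hatch form built on the
Lennard–Jones potential
$E_\mathrm{LJ} = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]$ with
$\epsilon = 0.2$ kcal/mol:

$$E_\mathrm{HPS}(r) = \begin{cases}
E_\mathrm{LJ}(r) + (1-\lambda)\epsilon, & r \le 2^{1/6}\sigma\\
\lambda\, E_\mathrm{LJ}(r), & r > 2^{1/6}\sigma
\end{cases}$$

so the pair hydropathy $\lambda$ scales the attractive tail while the
repulsive core is hydropathy-independent; the form is continuous at the
switch. $\sigma_{ij}$ and $\lambda_{ij}$ combine arithmetically from
per-residue values. Charged residues (D/E $-1$, K/R $+1$, H neutral by
default) add a Debye–Hückel term
$E_\mathrm{ele} = q_i q_j e^{-r/\lambda_D} / (4\pi\varepsilon_0
\varepsilon_r r)$. The relative permittivity is the product of two
empirical polynomials, $\varepsilon_r = e(T)\,a(C)$ with
$e(T) = 249.4 - 0.788\,T + 7.20\times10^{-4} T^2$ and
$a(C) = 1 - 0.2551 C + 5.151\times10^{-2} C^2 - 6.889\times10^{-3} C^3$,
valid for $T$ within (200, 400) K (outside the fit range the function
refuses). At 300 K and 0.15 M this gives 74.911. The Debye length is
$\lambda_D = \sqrt{k_B T \varepsilon_0\varepsilon_r / (2 N_A e^2 I)}$
with the ionic strength $I$ defaulting to the salt molarity (1:1 salt).

## Folded domains: structure-based model

Ordered regions use a Gō-type model: native contacts (residue pairs
with any heavy atoms within 4.5 Å in the reference structure, sequence
separation ≥ 3 to avoid double-counting bonded terms) interact through
$\varepsilon[5(\sigma/r)^{12} - 6(\sigma/r)^{10}]$ with the reference
bead–bead distance as $\sigma$; non-native pairs see a purely repulsive
excluded volume $\varepsilon_\mathrm{exv}(\sigma/r)^{12} -
(1/2)^{12}\varepsilon_\mathrm{exv}$, cut off at $r = 2\sigma$ where the
shift makes it vanish continuously ($\varepsilon_\mathrm{exv} = 0.6$
kcal/mol). We implement the $r^{-12}$ term with a positive sign: an
attractive inverse-twelfth "excluded volume" would be unphysical, and
only the repulsive form is continuous at the stated cutoff with the
stated shift. Local terms comprise harmonic bonds, statistical flexible
angle potentials $-k_BT\ln(P_\theta(\theta)/\sin\theta)$, Gaussian
wells on 1–3 distances, statistical flexible dihedrals
$-k_BT\ln P_d(\varphi)$ and Gaussian dihedral corrections. The
residue-type-dependent probability tables $P_\theta$, $P_d$ are not
part of the package's data; they are external inputs, and the
synthetic-parameter generator produces smooth, strictly positive,
normalized tables for testing. Interpolation uses natural cubic splines
of $\ln P$ for angles and periodic cubic splines for dihedrals, so that
energies and their derivatives are smooth; angles outside a table's
support are clamped to the boundary with a warning rather than
aborting the run.

A chain may mix models by region. Bonded terms whose particles span a
region boundary fall back to the HPS bond; angle/dihedral terms are
emitted only when the whole tuple lies in the ordered region.

## DNA

The three-site-per-nucleotide model: quartic bonds
$k^{(2)}\Delta b^2 + k^{(4)}\Delta b^4$, harmonic angles, backbone
dihedrals carrying a periodic cosine series plus a Gaussian correction,
an excluded volume $\epsilon[(\sigma/r)^{12} - 2(\sigma/r)^6] +
\epsilon$ truncated at $r=\sigma$, phosphate charges, and three
multi-body base–base terms built from a Morse potential split into a
repulsive branch (inner rise, zero beyond $r_0$) and an attractive
branch ($-\epsilon_M$ inside $r_0$, the outer branch beyond), modulated
by the angle function

$$f(\Delta\theta) = \begin{cases}
1, & |\Delta\theta| < \gamma\\
1 - \cos^2\!\big(\tfrac{\pi}{2\gamma}\Delta\theta\big), &
\gamma \le |\Delta\theta| \le 2\gamma\\
0, & |\Delta\theta| > 2\gamma .
\end{cases}$$

Stacking is $E^\mathrm{rep} + f(\Delta\theta_{BS}) E^\mathrm{attr}$;
Watson–Crick pairing adds the dihedral factor
$\tfrac12(1+\cos\Delta\phi_{BP}) f(\Delta\theta_1) f(\Delta\theta_2)$
on the attractive part only (the printed form of the pairing term
modulates only the attraction, and we follow it); cross-stacking is
$f(\Delta\theta_3) f(\Delta\theta_{CS}) E^\mathrm{attr}$. The site
tuples defining each angle are a package convention, documented in
`?dna_multibody_energy`: the angles are measured at the bases between
the flanking sugar sites. The 5′-terminal phosphate of each strand is
omitted, giving $3n - 1$ sites per strand — the layout that reproduces
1198 particles for a 200-bp duplex.

## Protein–DNA recognition

The position-weight-matrix (PWM) potential couples each DNA base to
DNA-binding Cα sites through a Gaussian in the base–Cα distance times
three angle modulations ($\theta_1$ at the base between its sugar and
the Cα; $\theta_2$, $\theta_3$ at the Cα between the base and the
preceding/following Cα). Each tuple also carries the
complementary-base partner term, so the effective depth is
$\epsilon_G(b, m) + \epsilon_G(\bar b, m)$. How PWM log-odds map onto
$\epsilon_G$ is not fixed by the model definition; the package accepts
the depth table as input and rejects evaluation with a missing entry.
Because this interaction couples particles that may live in different
subdomains without a symmetric partner list, its candidate list is
kept directed (no $i<j$ symmetrization).

# Neighbor lists and the cell grid

All non-bonded classes share one search pass. With per-class force
cutoffs $r_{c,\mathrm{exv}} \le r_{c,\mathrm{dna}} \le
r_{c,\mathrm{hps}} \le r_{c,\mathrm{ele}}$ (defaults 12/18/20/35 Å;
the engine refuses descending values) and a common buffer skin
$r_\mathrm{buffer} = 3$ Å, search thresholds are
$r_p = r_c + r_\mathrm{buffer}$. A pair closer than
$r_{p,\mathrm{exv}}$ enters the excluded-volume, DNA and HPS lists; a
pair between $r_{p,\mathrm{exv}}$ and $r_{p,\mathrm{dna}}$ the DNA and
HPS lists; beyond that, the HPS list only — so the class lists nest.
The electrostatic list is built separately over charged particles only.
Bonded 1–2 and 1–3 pairs are excluded from all lists (1–4 kept);
native-contact pairs are excluded from the class lists, since the Gō
term replaces their non-bonded interaction, but retain electrostatics.
We exclude them from the DNA class as well so the nesting invariant
holds exactly; the DNA class never evaluates protein pairs, so this is
a bookkeeping choice with no energetic effect.

Rebuilds are skipped while the maximum particle displacement since the
last build is below $r_\mathrm{buffer}/2$; this bound makes it
impossible for a pair to cross from beyond $r_p$ to within $r_c$
between rebuilds, which the suite checks empirically against brute
force on random walks. The cell grid uses the rule that a cell edge is
at least half of $r_{p,\mathrm{ele}}$ (cell counts
$\lfloor L / (r_{p,\mathrm{ele}}/2)\rfloor$ per axis), and boxes
smaller than $2 r_{p,\mathrm{ele}}$ per edge are rejected so the
minimum-image convention stays valid. At the system sizes this package
targets (hundreds to a few thousand particles), candidate generation
is an $O(N^2)$ minimum-image sweep in compiled code, which at these
sizes is faster than cell bookkeeping; the cell grid itself is the
substrate of the domain decomposition.

# Domain decomposition and load balancing

The cell grid is partitioned into one subdomain per (emulated) process
by recursive bisection along cell boundaries so the two sides carry
nearly equal particle counts; for odd counts the child targets split
$\lceil n/2\rceil : \lfloor n/2\rfloor$. Empty cells are distributed by
the same rule (weight zero), so sparse regions produce large, cheap
subdomains. Two split policies are available. `method = "greedy"`
chooses, at each level, the split position minimizing the deviation of
the left-side weight from its target fraction, with the split axis
taken as the longest edge of the current sub-box (ties x, y, z) — the
single-pass rule a production engine applies. The default on
desk-scale grids (≤ 512 cells, ≤ 64 subdomains) is `method = "exact"`:
a memoized search over all recursive axis-aligned bisections that
minimizes the maximum subdomain load. The greedy rule is measurably
suboptimal (one to ten percent on random instances) because a locally
balanced split can force an unbalanced descendant; at desk scale the
exact search costs milliseconds, so we make optimality the default and
keep the greedy rule for large grids, where the exact search would be
the bottleneck.

Pairs are owned by the subdomain of the cell containing their
minimum-image midpoint; floor binning makes boundary ties
deterministic. Halo plans list, for each subdomain, the foreign cells
within a given shell depth (Chebyshev distance on the periodic cell
grid, two shells for the electrostatic range under the cell-size rule),
grouped by owner, and are symmetric by construction. The correctness
surface replacing real message passing is the identity: summing
owned-pair energies over subdomains reproduces the serial energy to
$10^{-10}$ relative, for random systems and partitions.

Load balancing re-runs the partitioner on current per-cell counts at a
fixed step period, leaving the cell size untouched; the old partition
is kept if re-partitioning would not improve the imbalance
(max/mean of subdomain particle counts). Because forces are always
summed in global pair order, the partition never feeds back into the
physics: trajectories with different rebalance periods are
bit-identical, and the suite asserts this.

# Dynamics

Langevin NVT integration uses the BAOAB-family map, iterated with one
force evaluation per step:
kick $v \mathrel{+}= \Delta t\,F/m$, half-drift, exact
Ornstein–Uhlenbeck damping $v \leftarrow c_1 v + c_2 \xi$ with
$c_1 = e^{-\gamma\Delta t}$ and
$c_2 = \sqrt{k_B T (1 - c_1^2)/m}$, half-drift. At $\gamma = 0$ this
is velocity Verlet, which the microcanonical dimer test exploits.
Defaults follow standard CG practice: $\Delta t = 10$ fs,
$\gamma = 0.01$ ps⁻¹. Units are kcal/mol, Å, fs, Da; the conversion
1 Da Å²/fs² = 2390.0574 kcal/mol links kinetic and potential energy,
$k_B = 0.0019872041$ kcal/mol/K, and the Coulomb factor is 332.0716
kcal·Å/(mol·e²).

Systems whose force field reduces to harmonic bonds + HPS +
electrostatics run through a compiled chunked integrator that advances
until the buffer criterion fires; everything else takes a per-step R
path through the same term implementations that the finite-difference
oracles exercise. Thermostat noise in the compiled path is
counter-based (a splitmix64 hash of seed, absolute step and particle
index feeding Box–Muller), so the random stream is a pure function of
(seed, step, particle): trajectories are independent of chunk
boundaries, neighbor-list rebuild timing and the rebalance schedule,
and identical seeds give bit-identical runs. Velocities initialize
from the Maxwell–Boltzmann distribution at the target temperature
using the recorded seed.

# Droplet analysis

Chains are clustered with DBSCAN using either neighborhood definition
from the droplet literature: *contact* (two chains are neighbors when
any inter-chain residue pair is within 10 Å) or *center of mass* (COM
distance below $\varepsilon$). A chain is a core point when its
neighborhood, itself included, has at least `min_pts` members; border
chains join the first-discovered cluster; clusters smaller than
`min_cluster_size` are relabeled noise as a post-filter, since
standard DBSCAN lacks that parameter. The published analysis values
($\varepsilon = 0.5$ in contact units, min_pts 20, min_cluster_size
100 for two-droplet systems; 50 Å / 5 / 50 for multi-droplet systems)
are the documented defaults; toy-scale tests pass proportionally
smaller values. The stated contact convention reads as an inverted
distance (1 when touching); implementing the neighborhood directly as
"chains in contact" reproduces the intended clustering.

Mixing of two initial droplet populations is tracked through
$D_{IJ}$, the mean COM distance over all chain pairs with one chain
from population $I$ and one from $J$ (self-pairs excluded), and the
mixing coordinate $m = \sqrt{D_{11} D_{22}}/D_{12}$: two separate
droplets of radius $R$ at center distance $d$ give roughly $R/d$, and
complete mixing gives $m \approx 1$. The droplet shape coordinate is
$\eta = \max(d_x/d_y, d_y/d_x) + \max(d_y/d_z, d_z/d_y) +
\max(d_z/d_x, d_x/d_z) \ge 3$, with equality for any axis-symmetric
mass distribution. The extents $d_x, d_y, d_z$ are not pinned down by
the defining expression; we use per-axis standard deviations about the
droplet COM, which makes $\eta = 3$ exact for spherical symmetry and
is robust to outliers, with coordinate ranges available behind
`use_range = TRUE`. Extents are measured along the box axes (a
principal-axes variant would add rotation invariance but changes the
reported numbers; the invariance test is accordingly restricted to
translations and axis permutations, which hold exactly). COMs under
periodic boundaries use the circular-mean method per axis, so droplets
straddling the boundary are handled without unwrapping heuristics.
Density profiles are time-averaged slab histograms normalized per slab
volume.

# Synthetic systems

The generators replace slow compress-and-equilibrate preparation with
direct seeded packing: chains are grown as self-avoiding random walks
with exact 3.8 Å bonds, chain COMs uniform in a ball, and a global
minimum bead separation enforced by rejection. Two-droplet setups
place two such droplets along z with a chosen surface gap; multi-
droplet boxes place non-overlapping spheres by rejection sampling
below a 0.3 volume-fraction cap. Every generator is a deterministic
function of its seed.

What the fixtures do and do not emulate: packed droplets have roughly
uniform interior density and sharp surfaces, whereas equilibrated
condensates show surface enrichment/depletion, an equilibrated dilute
phase, and chain conformations drawn from the interacting ensemble.
Tests passing on these fixtures therefore validate the machinery —
energies, forces, list bookkeeping, decomposition identities,
clustering and metrics — not the thermodynamics of any real protein.

The two-droplet fusion demonstration uses a deliberately small, fully
specified condition set chosen once: 40 chains of 10 identical
uncharged beads ($\sigma = 6$ Å, $\lambda = 1$, mass 100 Da — maximal
stickiness so droplets are robustly stable), droplet radius 24 Å with
a 10 Å surface gap in a 150×150×220 Å box, packed at 5 Å minimum
separation; $T = 250$ K, $\Delta t = 10$ fs, $\gamma = 0.01$ ps⁻¹,
HPS/electrostatic cutoffs 20 Å, $2\times10^5$ steps, three seeds. The
mixing coordinate starts near $R/d \approx 0.45$ and relaxes toward 1
as the droplets merge; the suite requires the last trajectory quarter
to exceed the first in at least two of three seeds.

# Numerical choices and degenerate inputs

* All piecewise forms are continuous at their knots (HPS switch at
  $2^{1/6}\sigma$, Morse split at $r_0$, $f(\Delta\theta)$ at $\gamma$
  and $2\gamma$, both excluded-volume forms at their cutoffs); the
  suite checks each to $10^{-10}$.
* Analytic forces are validated against central differences
  (step $10^{-5}$, tolerance $10^{-5}$ relative / $10^{-8}$ absolute)
  for every term, including the multi-body DNA and PWM terms on all
  participating sites.
* Collinear angle geometry (undefined angle gradient) zeroes the
  modulation force contributions with a warning instead of producing
  NaNs; non-finite forces or energies abort with the particle or class
  named.
* Dihedrals live on $(-\pi, \pi]$ with minimum-image angular
  differences, so Gaussian dihedral wells behave correctly across the
  branch cut.
* The kd-tree tie-breaks are fixed (axis order x, y, z; smallest split
  index; first optimal split in the exact search), making partitions
  deterministic for identical inputs.
* Single-particle chains, empty systems, zero-step runs and empty
  trajectory frames are all defined and tested rather than rejected.

# Problem sizes

The suite runs everything at sizes chosen for completeness per CPU
minute: force-term oracles on scalars and few-site tuples;
neighbor-list and decomposition identities on 120–500-particle random
systems; grid-partition oracles on up to 6×4×4 cells with 8
subdomains (where the exhaustive bisection search is cheap);
equipartition over $10^5$ Langevin steps; the fusion demonstration at
the 400-bead condition above. Particle-count checks construct the
300,146- and 2,565,178-particle replicated topologies in full (tables
only, no dynamics).

# Known limitations

* No real parallel execution: the decomposition is verified
  in-process; halo plans are data structures, not messages.
* NVT only; no constant-pressure ensemble, slab-geometry pressure
  analysis or replica exchange.
* The HPS/structure-based split assigns disordered-ordered protein
  pairs to the HPS class (keeping droplet cohesion across region
  boundaries); other engines make other choices, and the class masks
  are localized in one place if a different convention is needed.
* Flexible-table potentials ship only as synthetic fixtures; using
  published statistical tables requires supplying them as inputs.
* The PWM depth table is an input; no log-odds-to-energy calibration
  is provided.
* Truncated (unshifted) non-bonded potentials at the class cutoffs, as
  in the source models; energy is not continuous at $r_c$ (the lists
  and buffer guarantee no pair is ever missed, not continuity).
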