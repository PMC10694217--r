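---
title: "Methods: comparative evolution of far-red-light photosystem I"
author: "frlpsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative evolution of far-red-light photosystem I}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frlpsi)
```

# Scope and model

`frlpsi` asks two linked questions about far-red-light (FRL) photosystem
I in cyanobacteria: *which residues distinguish the FRL-specific subunit
paralogs (PsaA2, PsaB2, PsaF2, PsaJ2, PsaI2, PsaL2) from their
visible-light (VL) isoforms*, and *which of the structural features built
from those residues — chlorophyll-f binding sites, the rotated A0B
electron-transfer chlorophyll — were already present in the common
ancestor of the FRL paralogs*. The package combines four method layers:
a column-wise specificity rule on grouped alignments, marginal ancestral
sequence reconstruction (ASR) on a fixed phylogeny, rigid-body structural
geometry, and a residue-evidence rule that converts the first three into
per-site ancestral yes/no calls.

# The specificity rule

For each alignment column the residues of the FRL and VL groups are
tallied separately (raw sequence counts over non-gap, non-X characters;
outgroup rows are ignored). The column is

* `GAP_DOMINATED` when either group has a gap fraction above
  `max_gap_fraction` (default 0.50);
* `GROUP_SPECIFIC` when, after dropping residues at within-group
  frequency at or below `max_noise_freq` (default 0.05), the FRL set is
  non-empty and disjoint from the VL set, **and** the FRL set is a single
  residue at frequency ≥ `min_frl_dominance` (default 0.90) or a subset
  of one conservative-substitution class (ILVM, FYW, ST, DE, KR, NQ)
  whose combined frequency passes the same bound;
* `SHARED_CONSERVED` when one residue dominates both groups;
* `VARIABLE` otherwise.

The thresholds are the tunable surface of the rule. The dominance default
of 0.90 with similarity classes enabled was chosen so that the motifs the
method must recognise — a Val/Ile group replacing a conserved Thr, a Ser
replacing a Gly, a Gln replacing an Ile — classify as specific while a
Trp→Phe replacement present in only half the FRL sequences does not. The
noise threshold of 0.05 tolerates one stray sequence in thirty (a typical
curated paralog set) without breaking disjointness. Frequencies
deliberately use raw counts rather than phylogenetic down-weighting: the
rule then reads exactly like a by-eye alignment audit, and the effect of
duplicated sequences is explicit (a duplicated minority variant can
legitimately flip a call; the tests assert this behaviour rather than
hide it).

One consequence of the gap rule deserves emphasis: a column occupied
only by FRL sequences (an FRL-specific *insertion*, such as the
five-residue loop carrying the B30 H-bond donor in PsaJ2) has a VL gap
fraction near 1 and is therefore reported `GAP_DOMINATED`, not
`GROUP_SPECIFIC`. Insertions are better assessed on the FRL-subtree
alignment, where the reconstruction includes the inserted columns; in the
shipped site fixtures the B30 site is accordingly supported by its
substitution residues (the PsaF2 Tyr donor and its PsaB2-Glu / PsaJ2-Leu
stabilizers) rather than by insertion columns.

# Ancestral reconstruction

The substitution model is the standard reversible amino-acid chain: a
symmetric exchangeability matrix `s` and equilibrium frequencies `π` give
`q_ij = s_ij π_j`, with rows summing to zero and the matrix scaled to one
expected substitution per site. LG is the default (exchangeabilities and
frequencies from phangorn's model collection); Poisson (uniform) exists
mainly because it admits closed-form and enumeration oracles. Transition
matrices come from the symmetric eigendecomposition of
`diag(√π) Q diag(1/√π)`; tiny negative entries from eigen round-off are
clipped and rows renormalised (deviations are below 1e-14, and the tests
check stochasticity at 1e-10). Among-site rate variation is available as
equal-probability discrete-gamma categories but is off by default: the
consumer of the reconstruction is conservation scoring, which uses only
the MAP state and is robust to mild rate mis-specification; shape
estimation is a possible extension, not a need.

Likelihoods use Felsenstein pruning with per-site rescaling. The marginal
posterior at an internal node combines the pruning conditionals below the
node with an outside (pre-order) pass through the rest of the tree,
`P(x | data) ∝ L_below(x) · L_above(x)`, averaged over rate categories
weighted by their site likelihoods. The MAP sequence takes the
highest-posterior state per site with alphabetical tie-break. Gaps and X
are missing data (all-ones conditionals), not a 21st state. The FaRLiP
ancestor is specified as the MRCA of the FRL-labelled leaves, computed
from labels rather than node names so that relabelled trees need no
editing.

Correctness is anchored three ways: site likelihoods and posteriors equal
brute-force enumeration over all internal-state assignments on small
trees (tolerance 1e-10); total log-likelihoods equal `phangorn::pml` on
simulated 8-leaf data; and the Chapman–Kolmogorov, detailed-balance and
pulley-principle (re-rooting invariance) identities hold at 1e-8–1e-9.

## What recovery the simulation harness supports

The ASR test harness simulates sequences down a random rooted tree
(default 12 leaves, 300 sites, branch lengths uniform on 0.05–0.3
substitutions/site) and scores how often the reconstructed root MAP state
matches the simulated truth. At these branch lengths the measured
recovery is 75–89% across seeds, and the *expected* accuracy of the
Bayes-optimal estimator — the mean of the per-site maximum posterior,
which the MAP estimator attains — is about 0.84. Higher recovery targets
are therefore unreachable at this divergence for any method, which is
worth keeping in mind when comparing against round-number expectations:
recovery is a property of the tree depth, not of the reconstruction
code. Shallower trees (e.g. branches scaled by 0.1) push recovery above
95%, and the monotonicity of posterior mass in branch length is itself a
tested invariant.

# Structural geometry

Superposition is the Kabsch algorithm (SVD of the covariance of matched,
centred point sets, reflection excluded), applied *locally*: backbone
atoms (N, CA, C, O) within 12 Å of the reference cofactor are matched and
fitted, so that a cofactor's motion is measured against its own protein
cage rather than against whole-complex lattice differences. The
quaternion (Horn) method serves as an independent oracle in the tests
(agreement 1e-8 in RMSD).

The rotation of a chlorophyll between two structures is reported as a
transparent three-part decomposition rather than a single opaque number:
(i) the angle between the in-plane NA→NC axes of the two tetrapyrroles
after projecting both into the plane bisecting the two macrocycle planes;
(ii) the angle between the plane normals; (iii) per-ring centroid shifts,
whose argmin is the pivot ring. Ring membership follows
chemical-component-dictionary naming (pyrrole rings A–D with nitrogens
NA–ND, isocyclic ring E with the 13¹-keto oxygen OBD) and is
configuration, since deposited files can differ. Plane fits are total
least squares (smallest singular vector), with the normal sign fixed by
the NA/NB/NC cross product.

A measured angle is worth calling a rearrangement only against the
baseline wobble of equivalent coordinates; `rotation_threshold()`
implements the mean + 2 SD of angles measured between baseline (e.g. all
VL) structures at the same site.

Hydrogen bonds are inferred from heavy atoms only, because deposited
models carry no hydrogens: donor/acceptor N, O, S pairs within 3.5 Å,
excluding covalent (< 2.2 Å) and 1–3 pairs, with the acceptor-side angle
(antecedent–acceptor···donor) required to fall in 90–180°. Bond quality
is |angle − 120°|, the deviation from the near-optimal sp² acceptor
geometry of a keto oxygen; `compare_hbond_quality()` pairs bonds across
structures by role and reports which side sits closer to optimal, with
differences under 0.5° treated as ties.

# Clustering

Group-specific residues mapped onto a structure are clustered by single
linkage at a 15 Å Cα cutoff — equivalently, connected components of the
distance graph, and the tests assert that equivalence on every run.
Single linkage is the right shape prior here because the empirical
clusters span the membrane: elongated chains that centroid-based methods
would fragment. Components below `min_size` (default 5) are reported as
`sparse` rather than numbered, matching the observation that a few
specific residues scatter outside the main clusters. Both parameters are
exposed.

# Ancestral site calls

A candidate chlorophyll-f site is configured as a set of supporting
residues with roles: `hbond_donor` and `cavity` residues are *required*
(each must be group-specific and ancestral-conserved), `stabilizer`
residues contribute as a fraction (default threshold 0.5). This encodes
the reasoning used for the eight candidate sites: a site whose donor
network is fully ancestral is called Y; a site whose cavity replacement
is both non-specific (half the extant sequences) and non-ancestral is
called N even though extant structures show the feature; a site whose
backbone donor is ancestral but whose surrounding loop is mostly derived
is called N under the stabilizer rule. The extant structure rows of the
site matrix are an *input* evidence table shipped as a fixture; only the
`Ancestral` row is computed. Flip-sensitivity is tested exhaustively:
negating any single required residue's conservation flag flips a Y call
to N.

# Synthetic data: what it does and does not show

The generators define the study conditions for all tests:

* `generate_grouped_alignment()` — 30 FRL + 30 VL sequences × 200
  columns, i.i.d. LG-frequency background shared across groups, 10
  planted disjoint specific columns (optionally as similarity-class
  mixtures), and an emitted true ancestor that retains a configurable
  fraction (default 0.7) of the planted residues. Planted columns
  satisfy the default rule *by construction*, so classifier sensitivity
  is a check of correctness, not of statistical power against noise.
* `generate_tree_and_sequences()` — random or balanced topologies,
  branches uniform on 0.05–0.3, full internal-node truth.
* `generate_rotated_cofactor_pair()` — an idealized planar chlorin
  (CCD-style atom names, built in code) inside a pseudo-backbone shell,
  rotated by a known angle about a chosen ring centroid, with optional
  Gaussian coordinate noise (0.05 Å for the Monte-Carlo check, a typical
  coordinate uncertainty for good cryo-EM maps).
* `generate_cluster_positions()` — Gaussian blobs (10 points, 4 Å
  spread) separated by 60 Å.
* `generate_site_demo()` — per-subunit alignments whose planted columns
  follow the qualitative evidence pattern of each candidate site, so the
  eight ancestral calls emerge from the rules.

What passing these tests does *not* show: real alignments have
phylogenetic correlation, compositional heterogeneity and alignment
error, none of which the i.i.d. background emulates; real structures
have correlated coordinate error, alternative conformations and
unmodeled loops; and the synthetic chlorin mimics only local tetrapyrrole
geometry. Quantities measured on the synthetic conditions (a sensitivity
of 1.0, a false-positive rate of 0) are ceilings that real, noisier data
will not reach.

# Numerical choices and degeneracies

* Eigendecomposition tolerance: transition-matrix rows are renormalised
  after clipping; stochasticity asserted at 1e-10.
* Per-site max rescaling in both pruning and outside passes prevents
  underflow on deep trees.
* Consensus and MAP ties break alphabetically; cluster labels order by
  size, then by smallest member index.
* Superposition requires ≥ 3 non-collinear pairs (second singular value
  test); plane fits require ≥ 3 non-collinear atoms.
* Redundancy reduction orders sequences by length (ties: id), computes
  identity on a global alignment (match +1, mismatch 0, linear gap −1)
  normalised by the shorter ungapped length, and is idempotent and
  monotone in the threshold — both tested. "Fragmented" sequences are
  those under 70% of the median length, a choice that removes partial
  database entries without touching genuinely short subunits.
* Pipeline TSV outputs round floating point to 6 digits so that reruns
  of an identical resolved configuration are byte-identical.

## Problem sizes

The shipped tests and the acceptance script use the generator defaults
above (60-sequence alignments, 12-leaf/300-site simulations, 50-seed
rotation Monte Carlo, 20 classification replicates). These sizes give
stable statistics for every quantity reported while keeping a full run
in the low minutes on a single core; all of them scale up by argument if
finer estimates are wanted.

# Known limitations

* The specificity rule is a frequency heuristic, not a test with error
  control; its thresholds are exposed precisely because reasonable
  alternatives (e.g. 100% within-group identity) exist.
* FRL-specific insertions require subtree-based reconstruction to be
  scored for ancestral conservation (see above).
* ASR assumes the input tree and branch lengths are correct and shares
  the usual marginal-reconstruction bias toward high-frequency states.
* H-bond detection without hydrogens cannot distinguish donor from
  acceptor when both atoms carry lone pairs and protons; orientations
  are reported whenever the acceptor-side geometry is admissible.
* The site-call rule treats support residues as independent; correlated
  evolution among them is not modelled.
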