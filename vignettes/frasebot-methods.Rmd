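---
title: "Fragment seeding from structural environments: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment seeding from structural environments: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The method

Structure-based hit finding usually starts from a known binding site and a
docking engine. `frasebot` takes a different route: it assumes that a ligand
fragment observed in a high-affinity crystal complex will "like" any protein
environment that closely resembles the one it was crystallised in. The unit
of knowledge is the **FRASE** (FRAgment in Structural Environment): a
chemically sound ligand fragment together with every protein residue having
at least one heavy atom within 4.5 Å of it. A database of such units,
harvested from many complexes, can then be transplanted onto a new target:

1. **Match.** Residue triplets — three residues whose Cα atoms form an
   approximately equilateral triangle with sides in [8, 12] Å — are
   enumerated both in each database FRASE and in the target protein. Each
   residue is encoded as a many-hot 11-bit property string (charge, H-bond
   donor/acceptor capacity, aromaticity, three hydrophobicity and three
   volume positions); the three strings concatenated in all six orders give
   a family of 33-bit fingerprints whose lexicographic minimum is an
   order-invariant hash key. Two triplets match iff their keys are equal.
2. **Align and seed.** For every match, the three Cα pairs define a
   least-squares rigid superposition (Kabsch, proper rotation only) that
   transplants the database fragment into the target frame.
3. **Re-cut and score.** A target-based FRASE is cut around the seeded
   fragment (same 4.5 Å rule, environment now from the target) and scored
   by a neural network that estimates whether the fragment's pose looks
   like a true crystallographic FRASE rather than a decoy. The input is a
   377-dimensional interaction fingerprint: for every (ligand atom, protein
   atom) pair within 10 Å, a Gaussian weight `exp(-(d - 3)^2)` is
   accumulated into the cell indexed by the pair's (ligand type, protein
   type) combination — 29 ligand types × 13 protein types = 377 cells.
   The weight peaks at 3 Å, the canonical contact distance, and is cut (not
   tapered) at 10 Å.
4. **Filter and condense.** Survivors must not collide with the protein
   (min heavy-atom distance ≥ 1 Å), must be buried (on average ≥ 5 protein
   atoms within 5 Å per fragment atom) and must score ≥ 0.4. They are then
   converted into typed pharmacophoric features (HBA, HBD, Pos, Neg, Ar,
   Hyd), clustered per type under a 3 Å diameter bound, and the most
   populous/dense cluster centroids are assembled into a 3D pharmacophore
   query for downstream library screening. The query export is the
   hand-off point; running commercial screening or docking tools is out of
   scope.

# Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| environment radius | 4.5 | Å | FRASE cut-out (inclusive boundary) |
| triplet edges | [8, 12] | Å | near-equilateral triangle window (inclusive) |
| fragment weight window | [50, 300] | Da | retention after fragmentation, open valences H-capped |
| collision minimum | 1.0 | Å | seeded-pose clash filter |
| buriedness | ≥ 5 atoms in 5 Å | – | mean over fragment heavy atoms, inclusive |
| fitness threshold | 0.4 | – | nativeness score cut |
| cluster diameter | 3.0 | Å | max pairwise member distance per feature cluster |
| decoys per true FRASE | 2 | – | training class ratio |
| network | 377–32–16–1 | – | ReLU hidden layers, sigmoid output |
| training | 500 epochs, batch 50, ADAM | – | binary cross-entropy, no class reweighting |

All are exposed through `pipeline_config()` and the individual function
arguments; defaults equal the values above and the configuration hash is
recorded in pipeline logs.

# Design choices where the design was open

**Boundary conventions.** Every distance threshold is inclusive ("within
4.5 Å" keeps a residue at exactly 4.5 Å). Inclusive bounds are the testable
choice and are applied uniformly (edges, burial, fitness).

**"Approximately equilateral".** Operationalised as: all three edges in
[8, 12] Å, no additional aspect-ratio constraint. The phrase adds no second
parameter, and the 8–12 window already caps the aspect ratio at 1.5.

**Triplet matching is exact key equality.** A fingerprint hash supports
only exact lookup; no tolerance parameter exists in the encoding. Because
bit-equality does not guarantee geometric congruence within the edge
window, `screen_target()` gates alignments on the superposition residual
(default `rmsd_max` 1 Å, configurable to `Inf`); grossly distorted
alignments would otherwise flood the scoring stage only to be removed by
the collision filter.

**Residue property table.** The shipped 20-row table follows the published
column order (charge pair, HBA, HBD, aromatic, hydrophobic×3, volume×3).
As printed, the two charge columns are inconsistent for the five ionizable
residues (basic residues carry the bit under the negative column and vice
versa); the shipped table assigns ARG/LYS/HIS → positive and ASP/GLU →
negative. Since one table encodes both database and target, matching
results are invariant under either reading; the chemically correct one
aids interpretability. The verbatim printed rows are preserved in a source
comment. Only the 20 standard residues with a Cα participate in triplets.

**Atom-type perception.** The 29 ligand and 13 protein type names are
fixed vocabulary; their perception rules are not published. Ligand-side
rules are implemented as documented graph predicates over the package's
molecule model (elements, bond orders, smallest rings, implicit
hydrogens): e.g. *Hetero* = any non-carbon heavy atom; *Vinyl* = carbon in
a non-aromatic C=C; *Carboxylate Oxygen* = oxygen on a carbon bearing two
oxygens at least one of which is doubly bonded. Protein-side types come
from a fixed residue/atom-name lookup (backbone N = amide donor, ASP/GLU
carboxylates negative, LYS/ARG amines positive, HIS imidazole both donor
and acceptor, ring carbons aromatic). An atom may carry several types;
Equation-style Kronecker semantics let a multi-typed pair contribute its
weight once per type pair. Aromaticity uses a deliberately simple ring
rule (SDF aromatic orders, or 6-rings with three ring double bonds, or
5-rings with two double bonds and a heteroatom) adequate for drug-like
fragments; exotic ring systems may be under-perceived.

**Fragmentation.** Only acyclic single bonds are cut, every subset of at
most `max_cuts` (default 3) simultaneously; the cap bounds the
combinatorics and is harmless because fragments beyond 300 Da are
discarded anyway. When a cut bond touches a ring atom, the atom across the
cut (the α-atom) stays with the ring fragment — so a biphenyl cut yields
each ring plus the other ring's attachment carbon. Fragment weight is
computed with open valences hydrogen-capped, the minimal completion
consistent with a Da window on heavy-atom structures.

**Decoy placement.** Decoys swap the fragment of one FRASE into another's
environment. The swapped-in fragment is translated so its centroid
coincides with the original fragment's centroid and rotated so its
principal axes align (deterministic sign convention, proper rotation), with
no re-minimisation: the pocket context is preserved without invoking a
docking engine. Two decoys per true FRASE, matching the training ratio
implied by the published training counts (77,582 = 2 × 38,791); the
validation decoy pool size is left configurable because the published
validation counts do not follow the training ratio.

**Class imbalance** (1:2 true:decoy) is handled by plain unweighted binary
cross-entropy, as no correction is stated for the method.

**Cluster density.** "Dense" is defined as `size / (1 + mean
member-centroid distance)`; any monotone alternative can be swapped in.
The k per feature type is the smallest k whose k-means solution satisfies
the 3 Å diameter bound (k-means with 10 restarts, fixed seed, k grown from
1); the diameter reading of "maximum distance between cluster members" is
the stricter of the two possible readings (the centroid-distance reading
is available via the clustering radius check in tests).

**Query assembly.** The published query choice involved visual inspection
of pocket geometry. The default path therefore expects an explicit
centroid choice (`picks`); `run_pipeline()` falls back to the top-ranked
clusters (up to four) so automated runs still produce a query.

**Metal ions.** HETATM groups on a deny-list (waters, common ions,
cryoprotectants, buffers) never become ligands and are excluded from FRASE
environments by default; whether the original export kept ions inside
environments is unstated, so the exclusion is configurable at the loader
(`ligand_selector`).

# The synthetic fixture generator

Tests and the acceptance script run without any structure download. The
generator emulates exactly the features the pipeline consumes:

* a palette of nine small molecules (benzene, phenol, toluene, pyridine,
  furan, imidazole, cyclohexane, benzamide, benzoic acid) with idealised
  3D coordinates and full connection tables, jointly covering the
  aromatic/donor/acceptor/ionizable/hydrophobic perception rules;
* reduced rigid residue templates (backbone + representative side-chain
  heavy atoms with canonical PDB atom names) for 15 residue types, placed
  with controlled closest-atom distances, with side chains oriented away
  from the fragment so planted poses are clash-free;
* planted Cα triangles with sides inside [8, 12] Å guaranteeing at least
  one qualifying triplet per toy complex;
* a fingerprint-space construction for classifier tests: both classes
  share a sparse exponential background over the 377 cells and the true
  class shifts the mean of five fixed signal cells by 3 (unit variance,
  truncated at zero), giving a closed-form construction separability of
  `pnorm(3 * sqrt(5) / 2) ≈ 0.9996`.

What the fixtures do **not** emulate: real rotamer statistics, backbone
connectivity between residues, crystallographic packing, heteroatom
diversity of real ligands, or the correlation structure of real
interaction fingerprints. Passing tests therefore demonstrate algorithmic
correctness (geometry, encoding, bookkeeping, learnability), not predictive
power on real proteins.

# Numerical choices and degenerate inputs

* Superposition uses the SVD form of the three-point Kabsch problem with
  the reflection branch corrected to determinant +1; collinear Cα triples
  raise a "degenerate triplet" error (the in-plane normal is
  unconstrained).
* The distance weight is evaluated exactly; the jump at the 10 Å cap is
  intentional (the weight there is `exp(-49)`, numerically negligible).
* Fingerprints are accumulated as `t(A) %*% W %*% B` over many-hot type
  membership matrices; a literal double-loop oracle verifies agreement to
  1e-12 in the tests.
* Alternate locations resolve to the highest-occupancy conformer, ties
  alphabetically; hydrogens are dropped on read; only the first NMR model
  is used.
* k-means falls back to one-cluster-per-distinct-point when k reaches the
  number of distinct coordinates (k-means requires k < n), which trivially
  satisfies the diameter bound.
* Empty environments yield a zero fingerprint with a warning and are
  scored anyway but flagged; single-FRASE decoy generation and
  single-class training raise errors.
* Training, decoys, fixtures and clustering take explicit seeds; RNG state
  is saved and restored around every seeded routine so library calls do
  not perturb user RNG state.

# Problem sizes used in checks

The automated checks run scaled-down but structurally faithful problems:
bulk FRASE sets of 38,791 (the published training-set size) for the decoy
count contract, a 184,963-id split for the database bookkeeping, 2,000
true fingerprints (1:2 decoy ratio, two-thirds train / one-third holdout)
for the classifier recovery check — about a 20× scale-down from the
published training set, chosen to keep the full check under a minute while
leaving a comfortable margin over the 0.95 accuracy requirement — and toy
complexes of 5–8 environment residues for the geometric pipeline. The one
check that cannot run self-contained is the published target-side triplet
count (233 for the CIB1 chain of PDB entry 6OCX): it needs the deposited
structure, which the package does not ship; place a copy at
`inst/extdata/6OCX.pdb` and `triplet_benchmark()` (or the corresponding
test) will evaluate it.

# Known limitations

* Ligand bond orders are only available through SDF input; ligands read
  from PDB HETATM records get distance-perceived single bonds, which
  under-types aromatic and ionizable groups. Supply SDF when typing
  matters.
* The REOS-style reactive-group list is a small documented set of graph
  predicates, not a full SMARTS engine; it is meant as a filter scaffold,
  and the rule list is user-editable.
* The published end-to-end funnel counts for CIB1 (5,362 seeded → 726 →
  151 → 398 features → 76 clusters) depend on the authors' unpublished
  FRASE database and are treated as logged diagnostics, not reproduction
  targets.
* Fragment poses are rigid; no receptor flexibility, pose minimisation or
  symmetry-mate handling.
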