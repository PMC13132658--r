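---
title: "Consensus scoring of RNA decoy ensembles: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus scoring of RNA decoy ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

RNA 3D prediction pipelines emit pools of candidate structures ("decoys")
for one sequence. A decoy that agrees with many other decoys — both in its
global fold and in which bases it pairs — is more likely to be near the
native structure than one that agrees with few. `rnaconsensus` turns this
into a score in four steps.

**3D agreement.** For every unordered pair of decoys we compute the
TM-score over corresponding C1′ atoms,

$$T_{ij} = \max_{\text{superpositions}} \frac{1}{L}\sum_k
  \frac{1}{1 + (d_k/d_0)^2},$$

where $d_k$ is the distance between residue $k$'s representative atoms
after superposition, $L$ is the common target length, and
$d_0 = \max(0.3, 0.6\sqrt{L - 0.5} - 2.5)$ Å is the RNA distance scale.
Normalizing every pair by the same $L$ makes $T$ symmetric. Residues missing
their representative atom in either decoy are dropped from the sum but not
from $L$, so incompleteness penalizes.

**2D agreement.** Each decoy's base-pair map is extracted from its
coordinates (see the annotator below) or read from external pair-list
annotations. For two maps, the Interaction Network Fidelity is the
geometric mean of precision and recall over their pair sets,

$$I_{ij} = \sqrt{\frac{|TP|}{|TP|+|FP|}\cdot\frac{|TP|}{|TP|+|FN|}},$$

with matching on residue-index pairs (a strict mode also requires matching
categories; annotator label dialects differ, so it is off by default). Two
empty maps score 1 — agreement that nothing is paired — and exactly one
empty map scores 0; both conventions are configurable.

**Consensus.** $M = T \circ I$ element-wise, so 3D similarity counts fully
only where it is reinforced by consistent base pairing, and

$$Q_i = \frac{1}{N-1}\sum_{j \neq i} M_{ij}$$

is decoy $i$'s quality score. The `no_bp` baseline applies the same row
mean to $T$ alone; comparing the two variants isolates what the base-pair
emphasis contributes. Ranking sorts by $Q$ descending with ties broken
lexicographically by decoy id, making "arbitrary" tie-breaking
reproducible.

### Assumptions

* All decoys model the same sequence; residue correspondence is by ordinal
  position after sorting by (chain, residue number, insertion code), not by
  author numbering, because numbering dialects vary across predictors.
  Multi-chain targets are concatenated in chain-id order.
* Consensus scoring presumes the ensemble is not dominated by one wrong
  basin and that the target has a single dominant conformation; for
  bistable RNAs (e.g. riboswitches) agreement-based scores are ambiguous by
  construction.
* The measure is symmetric. An asymmetric user-supplied measure would need
  symmetrization before the element-wise product; the built-in TM-score
  with fixed $L$ and INF are both symmetric.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `representative_atom` | C1′, then C4′, then P | — | C1′ is the standard nucleic-acid trace atom; fallbacks cover sparse coarse-grained files. |
| `d0` | $0.6\sqrt{L-0.5}-2.5$, floor 0.3 | Å | RNA TM-score convention; the floor keeps short chains meaningful. |
| `c1p_min`, `c1p_max` | 8, 12 | Å | C1′–C1′ distance window of paired nucleotides (canonical pairs sit near 10.4 Å). |
| `hbond_max` | 3.5 | Å | Donor–acceptor heavy-atom contact cutoff. |
| `min_contacts` | 2 | — | Watson–Crick and wobble geometries form 2–3 such contacts. |
| `max_plane_angle` | 65 | degrees | Paired bases are roughly coplanar. |
| `min_separation` | 2 | residues | No adjacent-residue "pairs"; enforced within chains only, since ordinal separation across a chain break is meaningless. |
| `inf_floor` | 0.1 | — | Lower bound on $I$ before the product; see below. |
| `both_empty` | 1 | — | INF value when neither decoy has any pair. |

### The floor on I

Whether the 2D term should be allowed to annihilate the 3D term is a real
design choice. A decoy whose annotation is empty (too distorted for any
pair to be detected, or simply unannotated) has $I = 0$ against every decoy
that has pairs; its entire consensus row collapses and it ranks below
decoys that are much worse in 3D. We therefore floor $I$ at 0.1 by default:
a decoy with no usable 2D evidence falls back to down-weighted 3D consensus
instead of being erased. The floor binds only in that degenerate situation
— whenever all maps are non-degenerate (the realistic case for annotated
ensembles) every $I_{ij}$ exceeds it and $M = T \circ I$ holds exactly.
`inf_floor = 0` restores the strict product.

## The geometric annotator

The built-in annotator substitutes for external tools when none is
available. A pair (i, j) is emitted when all of the following hold: the
C1′–C1′ distance lies in [8, 12] Å; at least two donor–acceptor heavy-atom
contacts between the base edges are within 3.5 Å (donors: A-N6, G-N1/N2,
C-N4, U-N3; acceptors: A-N1/N3/N7, G-O6/N3/N7, C-N3/O2, U-O2/O4); the
best-fit base planes meet at ≤ 65°; and the residues are non-adjacent
within a chain. A–U and G–C pairs with purine-N1 to pyrimidine-N3 contact
geometry are `canonical_wc`, G·U pairs `wobble`, everything else
`noncanonical`. A base may join several pairs — base triples are real.
This is a distance-and-plane criterion, deliberately simpler than the
hydrogen-bond-geometry classifiers it stands in for; users wanting
MC-annotate/FR3D/RNAView semantics can feed those tools' pair lists through
`read_pair_annotation()`, and INF then uses them unchanged.

## The TM-score search

TM-score maximizes a non-convex objective, so the implementation seeds a
Kabsch superposition from contiguous fragments and iteratively
re-superposes on the residue pairs closer than a shrinking cutoff
(8 → 4.5 Å over five steps, then fixed until the aligned set is stable, at
most 20 iterations), keeping the best score seen under any visited
transform. For chains of ≤ 60 usable residues every contiguous fragment of
length ≥ 4 is used as a seed — on desk-scale problems this exhaustive
seeding is what makes the search agree with an independently coded
exhaustive oracle to machine precision, and the hot loop is compiled
(RcppArmadillo), so a 30-nt pair costs ~20 ms. Longer chains fall back to
fragments of length $n, n/2, n/4, \ldots, 4$ at stride $n/10$, trading a
provably exhaustive search for near-linear cost. We first tried sparse
seeding everywhere; on dissimilar 30-nt pairs it undershot the exhaustive
optimum by up to 0.02, which is why the dense regime exists.

Pairwise evaluations run once per unordered pair, in canonical
(lexicographic-id) argument order — an SVD-based superposition is symmetric
only up to rounding under argument swap, and canonical order makes ensemble
scoring exactly permutation-equivariant and bit-reproducible across worker
counts.

## The synthetic generator

`ideal_duplex()` builds the reference: each base pair is placed in the
standard base-pair reference frame (the complementary base rotated 180°
about x) and stacked with the fiber A-form rise (2.81 Å) and twist (32.7°),
displaced −4.4 Å from the helix axis. Base atoms include the full ring plus
the Watson–Crick edge substituents the annotator needs; the sugar–phosphate
backbone is reduced to C1′ plus schematic C4′/P offsets (the trace atoms
other modules use), not full ribose chemistry.

Two construction choices keep the designed pairing the *only* geometry near
the annotator's thresholds, so the closed loop (annotator recovers exactly
the designed pairs) is robust rather than knife-edged. First, the pair
inclination is set to 10°, the low end of the A-family range: at higher
inclination the minor-groove edges of stacking-diagonal neighbours approach
within ~3.5 Å of each other. Second, the default sequence alternates A/U:
A/U duplexes have no minor-groove donors, so diagonal neighbours cannot
form spurious donor–acceptor contacts at all (measured margins: designed
contacts ≤ 3.02 Å, nearest spurious ≥ 3.8 Å, most > 6 Å). Any ACGU
sequence may still be supplied explicitly.

`perturb_structure()` adds i.i.d. Gaussian noise (per coordinate, std σ)
to every atom and then a random rigid motion — σ = 0 is a pure rigid test
of superposition invariance. `disrupt_pairs()` rotates one partner base of
selected pairs 90–150° about its glycosidic bond: the hydrogen-bonding
geometry is destroyed while the C1′ backbone — and hence the TM-score — is
untouched. This creates decoys whose 3D and 2D quality are decoupled,
exactly the situation the base-pair emphasis is meant to detect.

`make_ensemble()` ties it together: the default study condition is a
12-decoy pool over three noise tiers (σ = 0.1, 1.0, 3.0 Å, four decoys
each) on a 15-bp (30-nt) duplex, with TM-score to the unperturbed reference
as ground-truth quality — a reference-based truth computable without any
external data. These sizes keep a full 10-seed parameter-recovery study
under a minute while the three tiers span near-native to unfolded.

What the generator does *not* emulate: loops, junctions, non-canonical
motifs, pseudoknots, realistic conformational sampling (no fragment
assembly or dynamics), or annotation noise of real tools. Passing the
closed-loop tests therefore shows the pipeline's internal consistency and
its behaviour under controlled distortion — not performance on real decoy
pools, which depends on ensemble composition in ways no synthetic duplex
captures.

## Evaluation harness

Predictions and ground truth are joined per (target, decoy). The composite
truth is $G = 0.3\,\mathrm{TM} + 0.3\,\mathrm{GDT\_TS} + 0.4\,\mathrm{lDDT}$
(no imputation: a missing component is an error). Because raw score
magnitudes vary with target length and pool difficulty, both predictions
and truth are min–max normalized within each target before pooling for the
global Pearson/Spearman; a constant vector maps to all 0.5, which keeps the
degenerate case in range without infinities. Per-target correlations are
averaged both arithmetically and via Fisher's z (correlations clipped to
±(1 − 10⁻¹²) before atanh); zero-variance targets are dropped from the
correlation averages with a reported count. Top-1 loss —
|truth(top-ranked) − truth(best)| — is computed on the raw
(post-orientation) truth, since normalization is a pooling device, with
predicted ties broken by decoy id. RMSD-like truth columns are negated so
higher is better everywhere. Note that a strictly monotone transform of
predictions leaves all per-target rank statistics unchanged, but the pooled
global Spearman only survives per-target *affine* changes: min–max
normalization is itself affine, not rank-based.

## Numerical choices and degenerate inputs

* Superposition needs ≥ 3 points; fewer is an error, as is a pair with
  fewer than 3 residues carrying representative atoms in both decoys.
* Altloc resolution keeps the highest-occupancy copy (ties: first
  encountered); only the first model of multi-model files is read.
* Modified nucleotides map to their parent base where identifiable
  (pseudouridine → U, 1-methyladenosine → A, …); unrecognized residues are
  dropped, keeping the alphabet closed over ACGU.
* Decoys inconsistent with the majority sequence of their directory are
  excluded with a warning; ensembles need ≥ 2 consistent members.
* Residue indices are 1-based everywhere — internally and in all emitted
  files — matching both R convention and the 1-based pair-list format.
* Matrices are validated to be symmetric within 10⁻⁹ with entries in
  [0, 1]; the diagonal is set to 1 by convention and never used by the row
  mean.
* All generator randomness is seeded and runs in a private RNG scope, so
  identical specs produce byte-identical PDB fixtures without touching the
  caller's RNG state.

## Limitations

* All-vs-all scoring is quadratic in ensemble size; pairwise work is
  parallelized over unordered pairs (forked workers, order-independent
  merge) but very large pools remain expensive.
* The built-in annotator is a geometric stand-in, not a replacement for
  hydrogen-bond-resolved classifiers; edge/orientation taxonomies
  (Leontis–Westhof classes) are out of scope, which is also why INF matches
  on pair identity by default.
* Consensus scores are relative to the pool: they assess support within the
  ensemble, not absolute accuracy, and inherit the pool's biases.
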