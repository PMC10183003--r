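---
title: "Difference contact network analysis of conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Difference contact network analysis of conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcna)
```

## The problem

Large multi-subunit assemblies such as TFIIH reorganize their internal
architecture when they switch functional contexts -- the same ten-subunit
machine unwinds promoter DNA in transcription initiation and scans
single-stranded DNA for lesions in nucleotide excision repair. Molecular
dynamics ensembles of such assemblies in different functional states are too
large to compare residue by residue. This package dissects them with
graph-theoretical tools: residues become network nodes, contacts become
weighted edges, and conformational transitions become signed changes in
contact probability between *dynamic communities* -- groups of residues that
move as coherent modules.

The analysis has four stages, and `runDCNA()` executes them in order:

1. **Per-state contact networks.** For each functional state's ensemble, the
   contact probability $P_{ij}$ of every non-adjacent residue pair is the
   fraction of frames in which the pair's minimum inter-residue distance is
   within the cutoff.
2. **Consensus network.** Edges are contacts whose occupancy meets a
   stability threshold in *every* state; each edge retains its per-state
   probabilities. Communities found here are modules that are stable in all
   functional contexts, so contact changes can be attributed to interfaces
   between well-defined modules rather than to shifting module definitions.
3. **Community detection.** The consensus network is subdivided with the
   (non-weighted) Girvan-Newman procedure under a modularity stopping rule.
4. **Difference networks.** For each configured transition A to B, per-edge
   $\Delta P_{ij} = P_{ij}(B) - P_{ij}(A)$ is aggregated over community
   pairs, yielding a coarse-grained map of which module interfaces gain
   (positive) or lose (negative) contacts.

## Data model

A topology PDB defines the *node table*: one node per residue that carries
its representative atom -- C$\alpha$ for amino acids, P for nucleotides.
Residues lacking the representative atom (a 5'-terminal nucleotide without a
phosphate, say) are skipped and reported. Residue identity is keyed by
`(chain, author residue number, insertion code)` everywhere, because
disease-mutation positions are quoted in author numbering; internal indices
are 1-based and never leak into files.

An `Ensemble` holds an $F \times N \times 3$ stack of representative-atom
coordinates plus an optional heavy-atom layer with an atom-to-node map. The
heavy layer exists because the contact criterion is heavy-atom-scale (see
below); every operation that only needs one point per residue (B-factors,
PCA, correlations) uses the representative layer.

Trajectories are read from DCD files or multi-model PDB; frames from
multiple files are concatenated in the order given and subsampled by a
stride. XTC is not parsed by any of the R structural toolkits this package
builds on and is rejected with a clear error; converting XTC to DCD upstream
(e.g. with `mdconvert` or `catdcd`) is the supported route.

## The contact model

Two non-adjacent residues are *in contact* in a frame when they are within
**4.5 A**, and a pair is a *binary contact* of a state when it is in contact
for at least **75 %** of the trajectory. Both numbers are exposed as
parameters (`cutoff`, `occupancyThreshold`) with those defaults. Choices the
contact rule does not pin down, and how this package resolves them:

* **Which atoms?** The default measures the minimum heavy-atom-to-heavy-atom
  distance between the residues: 4.5 A is a van-der-Waals-scale criterion,
  and C$\alpha$ pairs are rarely that close. A `representative` mode
  (C$\alpha$/P distances) is provided for node-level geometries and for
  ensembles without a heavy-atom layer.
* **"Non-adjacent".** Same-chain pairs with sequence separation $\le$ 1 are
  excluded (set to zero occupancy); inter-chain pairs are never excluded.
  This removes only trivially bonded neighbours. The separation is a
  parameter (`exclusion`).
* **Periodic boundaries.** None: inputs are assumed imaged and whole, as
  post-processed production MD normally is.

The threshold comparison is inclusive: occupancy exactly 0.75 qualifies.

## Networks and their weights

Two network flavours share the same machinery:

* **dCNA mode** (default): every pair with $P_{ij} > 0$ is an edge weighted
  by the occupancy itself. Subtraction of contact maps is interpreted as
  subtraction of the occupancy fractions, not of binarized maps --
  $\Delta P$ is a probability change, and thresholding before subtraction
  would discard exactly the partial-occupancy interfaces the difference
  analysis is about.
* **Covariance mode** (traditional community network analysis): edges are
  the binary contacts, weighted $w_{ij} = -\ln |c_{ij}|$ where $c_{ij}$ is
  the dynamic cross-correlation
  $\langle \Delta r_i \cdot \Delta r_j \rangle /
  \sqrt{\langle \Delta r_i^2 \rangle \langle \Delta r_j^2 \rangle}$
  of the representative-atom displacement vectors (the vector dot-product
  convention standard in residue network analysis, not a per-axis Pearson
  coefficient). Strongly coupled pairs get short "distances". A perfectly
  uncorrelated pair on a contact edge would have infinite weight; this is
  reported as an error naming the pair rather than silently clipped.

## Community detection and the stopping rule

`girvanNewman()` iteratively removes the edge of maximal betweenness.
Each time a removal splits a connected component, the induced partition is
recorded with its Newman-Girvan modularity

$$Q = \sum_c \left[ \frac{e_c}{m} - \left(\frac{d_c}{2m}\right)^2 \right]$$

evaluated on the *original* graph ($m$ edges, $e_c$ intra-community edges,
$d_c$ total degree of community $c$). Subdivision stops when a newly
recorded partition improves $Q$ by less than `stopDeltaQ` (default
**0.001**) over the previously recorded one, and the best-$Q$ partition
recorded so far is returned. This monotone-refinement reading guarantees
termination and reproduces the intended behaviour on the canonical cases: a
single clique is never split (the first split worsens $Q$, so the trivial
partition is kept), and a two-clique graph splits exactly at its bridge.
Whether the stopping-point partition or the best-$Q$ partition differ can be
inspected after the fact: the full dendrogram trace (every recorded
partition with its $Q$) is retained on the result.

Determinism matters for a pipeline whose outputs are compared across runs:
among equally maximal-betweenness edges, the lexicographically smallest
node-index pair is removed. Identical inputs therefore give byte-identical
outputs, which the test suite asserts.

Betweenness and modularity are unweighted by default, matching the
non-weighted algorithm; `useWeights = TRUE` switches both to weighted form
(betweenness treats weights as distances, which is the natural reading for
covariance-mode weights).

Two open choices are resolved as follows. The consensus *node* set is the
intersection of the per-state node sets (a DNA chain present in only one
state cannot anchor consensus edges); dropped keys are recorded on the
result. The consensus *stability threshold* defaults to 0.75 -- the one
occupancy threshold the contact rule defines -- but is configurable, and
deliberately so: a contact that climbs from 0.3 to 0.7 across a transition
never passes a 0.75-in-every-state filter, so difference analyses that focus
on reorganizing interfaces should lower `stabilityMinProbability` (the
acceptance runs use 0.05 for the sign-recovery check while keeping 0.75 for
community detection).

## Difference networks and the sign convention

$\Delta P$ is always *later state minus earlier state* for a transition
written A $\to$ B, so positive community-pair entries mean interactions
gained in the transition. `communityDelta()` sums edge $\Delta P$ over
community pairs (diagonal = within-community sums); the grand total over the
upper triangle plus diagonal equals the total edge $\Delta P$, a
conservation property asserted in the tests. `topChangedResidues()` ranks
nodes by the absolute value of their signed incident sum, keeping the sign
so gains and losses stay distinguishable; ties break by (chain, residue
number).

## Flexibility and global motions

B-factors use the crystallographic isotropic convention
$B_i = \frac{8\pi^2}{3} \langle \Delta r_i^2 \rangle$ on the superposed
representative coordinates. No superposition scheme is canonical; this
package uses a two-pass least-squares fit (rotation + translation, no
scaling): frames are fitted to frame 1, then refitted to the resulting
ensemble average. This removes global drift that a single fit to an
arbitrary frame would leave behind. The fit is idempotent and preserves all
intra-frame distances to numerical precision.

PCA diagonalizes the $3N \times 3N$ Cartesian covariance of the same
superposed frames (population convention, division by $F$, consistently
with the ensemble averages used everywhere else), with no mass weighting.
The "lowest" principal modes are the *largest-variance* eigenpairs, sorted
descending -- the essential-dynamics usage of "lowest". Mode signs follow a
deterministic convention (largest-magnitude component positive). The full
eigendecomposition is used directly; at node counts up to a few thousand an
iterative solver buys nothing. `modeArrowsByCommunity()` turns one mode
into per-node porcupine arrows annotated by community, with per-community
mean directions and amplitudes -- the representation used to contrast a
mobile translocase module against a rigidified core.

## Mutation interface mapping

A mutation is **interfacial** in a state when its residue node has at least
one network edge to a node of a different community, and the partner set is
the community pairs so connected. The criterion is graph adjacency rather
than visual proximity, is invariant under community relabelling, and reuses
the network the analysis already built (by default the consensus network,
whose partition labels every node; per-state networks can be passed
explicitly). Wild-type letters are cross-checked against the topology
residue names, with mismatches warned about but kept -- annotation tables
and structural models frequently disagree by one isoform offset, and
dropping records silently would bias the counts. Unresolved mutations are
carried through every report as `unresolved`, never dropped. The phenotype
vocabulary is closed to XP, TTD, XP/CS and XP/TTD; compound-heterozygote
context travels in a free-text note.

## The synthetic generator

MD ensembles of the real assemblies are microseconds long and not
redistributable, so validation uses synthetic ensembles whose ground truth
is planted by construction. `plantedSpec()` defines K communities of equal
size as tight clusters (radius 1 A) on a ring with adjacent-centroid
spacing $2 \cdot \text{cutoff} + 1$; the geometry guarantees, with bounded
uniform per-node jitter, that intra-community pairs are within the cutoff
and distinct communities are far outside it, deterministically rather than
with high probability.

* **Intra occupancy** below one is planted by per-node "out" excursions
  (the node jumps far outside the cutoff) with probability
  $q = 1 - \sqrt{p_\text{intra}}$, so every intra pair is in contact
  exactly when neither endpoint is out: occupancy $(1-q)^2 = p_\text{intra}$
  for every pair.
* **Inter occupancy** is carried by one dedicated bridge node per community
  per planted pair. With the pair's Bernoulli probability (drawn jointly for
  both bridges), the bridges jump to "near" positions inside the cutoff --
  chosen close enough to their home clusters that intra contacts survive the
  excursion. The planted occupancy is therefore
  $p_z (1-q)^2$ with $p_z = p_\text{inter}/p_\text{intra}$, i.e. exactly
  $p_\text{inter}$ (which is why $p_\text{inter} \le p_\text{intra}$ is
  required). Planted pairs must connect ring-adjacent communities; other
  pairings are geometrically infeasible at this layout and rejected.
* **Motions** are shared per-community Gaussian translations (amplified for
  designated mobile communities) plus bounded per-node jitter -- the minimum
  structure that makes intra-community correlations high, inter-community
  correlations low, and a mobile module separable by both B-factors and
  PCA mode amplitudes.
* **Heavy atoms** are the representative atom plus two 0.25-A offset
  satellites per node, so heavy-atom contact geometry is exercised; the
  planted statistics hold in both geometries at this offset scale.

Two known, deliberate approximations: when one community carries two
planted pairs, its two bridge nodes can fail to stay in mutual contact in
the rare frames where both are simultaneously "near" (a deviation of order
$p_z^2$, well under the test tolerances); and the shared Gaussian
translations have unbounded tails, so inter-pair occupancies are exact only
up to a tail probability of order $10^{-4}$ per frame at the default
amplitudes. Everything is drawn from one seeded generator with no global
RNG state leakage; the same seed reproduces coordinates bit-for-bit, and a
transition pair shares its topology and bridge assignment between states so
consensus analysis is well-posed.

What the generator does *not* emulate -- and hence what passing its tests
does not show about real data: physical force fields and energetics,
realistic protein geometry (clusters of radius 1 A are statistical tokens,
not folds), kinetics or autocorrelation in time (frames are i.i.d.),
partial-occupancy contact networks with heterogeneous degree, and the slow
collective modes of a real assembly. The generator validates the *graph and
statistics machinery*, not the biology.

## Problem sizes and numerical choices

The test and acceptance runs use K = 4 communities of 10 nodes at F = 500
frames for partition recovery (20 seeds), F = 1000 for sign recovery,
F = 5000 for occupancy convergence ($\pm 0.02$), F = 10000 for the Gaussian
B-factor limit (within 5 % of $8\pi^2\sigma^2$), and exhaustive
Bell-number enumeration up to 8 nodes as the modularity oracle. These sizes
put every stochastic check 3 or more standard errors inside its tolerance
while keeping the whole suite under a minute of compute.

Other numerical decisions: occupancies are exact rational counts (frames
hit / frames total), so oracle comparisons use exact equality; the
correlation matrix is symmetrized and unit-diagonal by construction and
PSD up to $10^{-8}$; eigenvalues are clipped at zero from below; B-factor
annotation clips to the PDB column range [0, 999.99] with a warning; and
all TSV/JSON outputs are written with deterministic ordering so reruns are
byte-identical.

## Limitations

* XTC input is not supported (no R-side parser); convert to DCD first.
* No Louvain/Leiden or spectral community detection; Girvan-Newman with the
  modularity stop is the method implemented, and at consensus-network sizes
  beyond ~10^4 edges its cost grows steeply.
* No hydrogen-bond, salt-bridge or energy-weighted contact definitions; no
  per-atom anisotropy; no mutation side-chain modelling or stability
  (ddG) prediction -- the mutation module maps positions onto community
  interfaces, nothing more.
* Headline community counts and modularities of the real TFIIH ensembles
  depend on trajectories that are not publicly deposited; the package's
  validation is therefore property-based on planted ground truth, and the
  acceptance report states recovered quantities on synthetic conditions.
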