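# dcna — difference contact network analysis of conformational ensembles

`dcna` is an R package for dissecting how large biomolecular assemblies
reorganize between functional states, using molecular-dynamics (or other)
conformational ensembles as input. It was built for the kind of question
posed by multi-functional machines such as TFIIH — which module interfaces
gain or lose contacts when the assembly switches from transcription
initiation to DNA repair, and where do disease mutations sit relative to
those interfaces? — but applies to any multi-state ensemble of a protein or
protein/nucleic-acid complex.

## The method

Residues are network nodes (represented by their Cα or P atoms); contacts
are edges. For each state's ensemble, the **contact probability**
*P<sub>ij</sub>* is the fraction of frames in which two non-adjacent
residues come within 4.5 Å (minimum heavy-atom distance); a pair is a
binary contact when *P<sub>ij</sub>* ≥ 0.75. The analysis then:

1. builds a per-state contact network weighted by *P<sub>ij</sub>*;
2. forms the **consensus network** of contacts stable in *every* state;
3. partitions it into **dynamic communities** by iterative removal of
   maximal-betweenness edges (Girvan–Newman), stopping when the modularity
   *Q* = Σ<sub>c</sub> [ e<sub>c</sub>/m − (d<sub>c</sub>/2m)² ] improves by
   less than 0.001 between recorded partitions;
4. computes per-transition **difference networks**
   ΔP<sub>ij</sub> = P<sub>ij</sub>(B) − P<sub>ij</sub>(A) and aggregates
   them over community pairs, so positive entries are interfaces gaining
   contacts in the A → B transition.

Alongside the dCNA core, the package provides covariance-based community
network analysis (edge weights *w<sub>ij</sub>* = −ln |c<sub>ij</sub>| on
binary contacts), B-factor profiles (B = (8π²/3)⟨Δr²⟩ after two-pass
superposition), Cartesian-covariance PCA with community-annotated porcupine
arrows, mapping of disease-mutation tables onto community interfaces, and a
synthetic multi-state ensemble generator with planted ground truth used for
all validation.

## A worked example

Two synthetic states of a four-community assembly share a topology; the
transition weakens two community interfaces by 0.25 and strengthens the
other two by 0.35 (planted ground truth).

```r
library(dcna)

spec <- plantedSpec(nCommunities = 4, nodesPerCommunity = 10, frames = 500,
                    intraContactP = 0.95,
                    interContactP = rbind(c(1, 2, 0.45), c(2, 3, 0.45),
                                          c(3, 4, 0.45), c(1, 4, 0.45)),
                    seed = 1)
tp <- generateTransitionPair(spec,
        deltas = rbind(c(1, 2, -0.25), c(2, 3, +0.35),
                       c(3, 4, -0.25), c(1, 4, +0.35)),
        labels = c("apo", "NER"))

Papo <- contactProbability(tp$stateA$ensemble)
Pner <- contactProbability(tp$stateB$ensemble)
Papo
#> ContactProbabilityMatrix: 40 nodes, 148 pairs with P > 0
#>   cutoff 4.50 A, exclusion 1, geometry 'heavy', 500 frames, state 'apo'

cons <- consensusNetwork(list(buildNetwork(Papo), buildNetwork(Pner)),
                         stabilityMinProbability = 0.05)
communities <- girvanNewman(cons)
communities
#> CommunityPartition: 4 communities over 40 nodes, Q = 0.7230
#>   dendrogram trace: 5 recorded partitions

dn <- differenceNetwork(cons, "apo", "NER")
round(deltaMatrix(communityDelta(dn, communities)), 2)
#>       1     2     3     4
#> 1 -0.27 -0.23  0.00  0.36
#> 2 -0.23  0.37  0.34  0.00
#> 3  0.00  0.34 -0.36 -0.27
#> 4  0.36  0.00 -0.27  0.04

head(topChangedResidues(dn), 3)
#>   key chain resno aggregate direction
#> 1 A:2     A     2     0.408      gain
#> 2 C:2     C     2    -0.380      loss
#> 3 B:2     B     2     0.352      gain
```

The detected partition matches the planted one exactly (communities 1–4 in
order of appearance), and the community-pair ΔP matrix recovers all four
planted interface changes with the right signs and close to the right
magnitudes (−0.23, +0.34, −0.27, +0.36 against planted −0.25, +0.35,
−0.25, +0.35); the top-changed residues are the planted bridge nodes. The
diagonal carries within-community occupancy noise summed over ~36 edges per
community.

For file-based runs, `runConfig()`/`readRunConfig()` plus `runDCNA()`,
`runStateProfile()` and `runMutationMap()` orchestrate the same steps over
PDB/DCD inputs and write TSV/GraphML/JSON reports; a thin command-line
wrapper lives at `inst/scripts/dcna.R`.

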