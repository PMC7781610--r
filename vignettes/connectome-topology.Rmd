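---
title: "Methods: topological characterization of weighted directed connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topological characterization of weighted directed connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(connectocore)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the tunable parameters and their
defaults, the numerical conventions, and the known limitations. It states
no empirical result that the test suite or the acceptance script does not
itself compute.

## The data model

The central object is a weighted directed graph of `n` cortical areas with
weights `w_ij > 0` for a projection from source `i` to target `j` (rows =
source, columns = target). Weights are FLNe-style fractions in (0, 1]:
the proportion of labeled neurons a tracer injection in the target
attributes to each source area. Two facts about such matrices shape the
design:

* **Zero is a measurement.** A literal `0` means a tested, absent
  projection; an untested pair is *missing*. The loader therefore treats
  empty cells and `NA` as missing and, under `pairwise_complete = TRUE`,
  greedily removes the node with the most untested entries until the
  remaining submatrix is fully tested. The greedy rule (rather than a
  one-shot "drop any row/column containing a missing value") is needed
  because a single untested pair would otherwise remove *both* endpoints,
  even when removing one node suffices.
* **Weights span orders of magnitude.** Path-based statistics use the
  order-reversing length transform `l_ij = -ln(w_ij / w_max)` (natural
  log of the max-normalized weight, the Brain Connectivity Toolbox
  convention), so the strongest edge has length 0 and absent edges length
  infinity.

## Null model and significance

All significance statements compare against ensembles of Maslov–Sneppen
rewired graphs: repeated double-edge swaps `(a→b, c→d) → (a→d, c→b)`,
accepted only when no self-loop or duplicate arc would result. This
preserves the binary in- and out-degree sequence exactly; weights travel
with the rewired arcs, so the weight multiset, total weight, and density
are also invariant, while the weight–endpoint association randomizes.
Defaults: 10 attempted swaps per edge (a field convention; the acceptance
rate is logged), 1,000 members for global metrics and rich club, 100 for
motifs and homology.

Empirical p-values use the add-one estimator `p = (r + 1)/(m + 1)`, which
never returns a literal zero; reference analyses often report the raw
proportion `r/m`, and the difference is at most `1/(m + 1)`. Two-tailed
values are `2·min(p_greater, p_less)` capped at 1. A consequence worth
remembering when calibrating: with `m` nulls the smallest achievable
two-tailed p is `2/(m + 1)`, so two-tailed tests at α = 0.05 require
`m ≥ 40`.

## Global statistics

* **Reciprocity** is the correlation of the off-diagonal weight matrix
  with its transpose around the common off-diagonal mean. It is 1 for any
  symmetric matrix and near 0 for rewired nulls.
* **Assortativity** is the Pearson correlation, over directed edges, of
  the source's out-degree/strength with the target's in-degree/strength
  (the out–in flavor). Regular graphs have zero endpoint variance and
  yield a flagged `NA`.
* **Clustering** is Fagiolo's directed-weighted coefficient on
  max-normalized weights with an elementwise cube root. The printed mean
  is scale-dependent, so the normalization choice is recorded in the
  output; an unnormalized variant is available.
* **Characteristic path length** summarizes all-pairs shortest paths on
  the length transform. The default summary is the arithmetic mean over
  reachable ordered pairs, with the unreachable-pair count reported; the
  harmonic mean (unreachable pairs contributing zero inverse distance) is
  available via `mean_rule`. The field's toolboxes describe the harmonic
  mean but compute the arithmetic mean over reachable pairs; we expose
  both rather than guess which convention produced any particular printed
  value.
* **Small-world indices** divide clustering and path length by their
  rewired-ensemble means: `γ = C/⟨C_rand⟩`, `λ = L/⟨L_rand⟩`,
  `σ = γ/λ`. The identity `σ·λ = γ` holds to machine precision and is
  asserted in the tests.

## Community detection

Modularity uses the directed (Leicht–Newman) null term,
`Q = (1/m) Σ_ij [A_ij − γ s_i^out s_j^in / m] δ(c_i, c_j)`, including the
diagonal of the null term (this makes `Q = 1 − γ/2` exact for two
disconnected complete digraphs under the true 2-block labels — a closed
form the tests pin down). The optimizer is a Louvain-style two-phase
greedy: randomized sweeps of local moves, then aggregation, until no gain;
it never symmetrizes the graph. Because the landscape is glassy, the
package follows the consensus-clustering recipe: many optimizer runs, a
co-assignment matrix, thresholding at `τ` (default 0.4; the co-assignment
matrix is re-used unthresholded if τ wipes it out entirely), and
re-clustering of the thresholded matrix until all runs agree.

The resolution sweep covers `γ ∈ [0.5, 2.2]` in steps of 0.1 by default
(the interval is the reference range; the step is ours). Well-defined
scales are reported as plateau centers: maximal contiguous grid intervals
wider than 0.2 in γ whose within-interval mean pairwise NMI exceeds the
90th percentile of all pairwise NMI values. The rule operationalizes
"wide regimes of near-maximal partition similarity" and both knobs are
exposed, since reasonable alternatives exist.

NMI uses arithmetic-mean entropy normalization, `2I/(H_a + H_b)`. When
both partitions are trivial (single community) both entropies vanish and
the value is defined as 0 by convention — the degenerate case carries no
information about agreement.

## Hubs and rich club

Participation coefficients follow the standard strength-fraction
definition per community, separately for afferents and efferents;
zero-strength nodes get participation 0 and a flag. Across resolutions,
nodes are rank-transformed within each consensus partition (average ranks
for ties) and ranks averaged — rank aggregation makes the profile
invariant to monotone transforms of the coefficient. Consensus partitions
(not all optimizer runs) enter the aggregation; this is configurable.

The rich-club curve removes, at each level `k`, all nodes with total
binary degree ≤ `k` and records the directed density of the surviving
subgraph. Reference descriptions are ambiguous between "remove ≤ k" (keep
degree > k) and "keep ≥ k"; the package defaults to keep-degree-> k (the
Colizza convention) with `keep_geq = TRUE` to flip. The curve is binary:
"density" is the stated statistic, not a weighted rich-club coefficient.
Normalization is against the per-k ensemble mean, significance per k is
one-tailed (greater), and the reported regime is the longest contiguous
significant run.

## Motifs

Motif classes are not a lookup table: the package enumerates all labeled
digraphs on 3 nodes, keeps the weakly connected ones, and collapses them
under the 6 vertex permutations. Class IDs follow the Brain Connectivity
Toolbox order, reproduced here by sorting classes lexicographically by
their canonical degree label (the three (out, in) degree pairs sorted by
out- then in-degree). Two anchors identify the convention: class 9 is the
chain of two reciprocal dyads and class 13 the fully reciprocal triangle.
The census counts *induced* subgraphs — each connected triple contributes
to exactly one class — since enrichment spectra in the connectomics
literature read as induced-triad frequencies; a partial-subgraph variant
is deliberately not offered to avoid silent convention mismatches.
The same enumeration machinery counts 2-, 3- and 4-node classes
(2, 13, 199), which the acceptance script reports.

## Persistent homology

The directed graph is symmetrized (elementwise max by default — the
weaker `mean` rule is available; a reciprocal pair should not be
penalized for asymmetry when building an undirected complex), undirected
edges are sorted by strictly decreasing weight with deterministic
lexicographic tie-breaks, and the clique complex grows edge by edge: a
(k+1)-clique enters when its last edge does. Simplices up to tetrahedra
(`max_dim = 3`) support homology in dimensions 0–2. Reduction is the
standard boundary-matrix column algorithm over GF(2), with the `V`
matrix maintained so that infinite bars also get representative cycles.

Two filtration axes are emitted per bar: the integer edge rank (used for
barcodes and for all null comparisons, since rank is comparable across
graphs with similar edge counts) and the metric value `-ln(w/w_max)`.
Representative cycles are the support of the reduced column at pairing
time — the cycle that dies — which approximates, but is not guaranteed to
be, a minimal representative just before death; exact minimal-cycle
search is out of scope and this approximation is the documented behavior.

Null comparison of cavities is not standardized in the literature, so two
defensible statistics are computed per dimension, neither claimed to be
canonical: (a) the number of long-lived bars, with "long" defaulting to a
quarter of the graph's own filtration length and infinite deaths capped
at one step past it; (b) the longest capped lifetime. Both get one-tailed
empirical p-values against the ensemble.

## The synthetic world

The generators state the world the tests live in:

* `generate_geometric`: nodes uniform in a 25 mm cube (the linear scale
  of a small primate cortex); directed edges accepted with probability
  proportional to `exp(-decay_rate·d)`, with a bisection-tuned global
  scale so the expected directed density hits the target (default 0.626,
  the density of the motivating tracer network); unidirectional pairs
  completed with probability `reciprocity_bias` (default 0.7); weights
  `exp(-decay_rate·d)` times lognormal noise with total σ = 1, of which
  70% of the log-variance is shared between the two directions of a pair.
  Defaults `decay_rate = 0.18` per mm puts roughly three e-foldings of
  weight decay across the box diagonal, matching the qualitative
  "several orders of magnitude over the distance range" shape of
  tracer weight–distance plots. The shared-noise fraction is what makes
  weight reciprocity high (≈ 0.6–0.7) while rewired nulls sit near 0.
* `generate_modular`: planted-partition block probabilities with a
  within/between ratio applied to both edge probability and expected
  weight, overall density held at the target; the planted labels ride
  along in `meta`.
* `generate_hierarchical`: two nested planted levels. The coarse contrast
  (`ratio = 6`) is deliberately larger than the additional sub-block
  contrast (`sub_ratio = 3`): with equal per-level contrasts the
  sub-block level dominates the modularity landscape at *all*
  resolutions and the coarse level is never the optimum, so a hierarchy
  that is supposed to be resolvable at two scales must be built with a
  dominant coarse level. This was established during design and is the
  reason the generator exposes two ratios rather than one.

What the generators do **not** emulate: cortical geometry beyond a
uniform box (no sheet topology, no laminar structure), the empirical
strength distributions beyond qualitative right-skew, spatially
correlated noise, and any cytoarchitectural gradients. A green test
therefore establishes that the *algorithms* behave correctly on networks
with the stated statistical structure — not that the generators are a
model of any real cortex.

## Numerical conventions and degenerate inputs

* All stochastic functions take integer seeds; ensembles and pipelines
  derive child seeds deterministically from a master seed, and repeated
  runs are bitwise identical (asserted in tests down to the serialized
  report).
* Zero-variance situations (reciprocity of a constant off-diagonal,
  assortativity of a regular graph, strength-ratio correlation of a
  symmetric graph) return flagged `NA` with a warning rather than a
  number.
* Nodes with fewer than two neighbors have undefined clustering and are
  excluded from the mean (count reported). Unreachable pairs are excluded
  (arithmetic) or contribute zero inverse distance (harmonic).
* Ties in the edge filtration are broken by sorted endpoint labels;
  repeated builds are identical.
* The consensus loop errors after 50 non-converged iterations rather
  than silently returning a mixture.

## Limitations

* Null models are rewiring-based only; strength-preserving, spatial, or
  cytoarchitecture-matched nulls are out of scope.
* The motif census stops at 3 nodes (the 199 four-node classes are
  counted combinatorially but not censused).
* Homology stops at dimension 2 and undirected clique complexes;
  directed flag complexes are not implemented.
* Exact minimal representative cycles are approximated by the reduction's
  pairing-time representative.
* The headline characteristic path length depends on an arithmetic-vs-
  harmonic convention choice that cannot be resolved without the original
  data; both are provided.
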