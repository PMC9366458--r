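---
title: "Methods: distances, mappings and their validation in cladospace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distances, mappings and their validation in cladospace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the definitions, the tunable parameters and why their defaults are what
they are, the numerical choices that make results reproducible, and the
limits of what the synthetic fixtures can demonstrate.

# Trees and splits

All inputs are cladograms: `ape::phylo` objects whose branch lengths, if
present, are discarded on import.  The package's unit of comparison is the
*split* — the bipartition A|B of the leaf set induced by an internal edge
of the unrooted topology.  A split is nontrivial when both sides hold at
least two leaves; a binary n-leaf tree has n − 3 of them.  Split
extraction is root-invariant: a degree-2 root is suppressed, so rooted and
unrooted representations of the same topology yield the same split set.

Rootedness is treated per operation, not per file: the Kendall–Colijn
distance, the total cophenetic index and the minimum implied gap require a
rooted tree (a bifurcating outermost node) and raise an error otherwise;
every other operation treats its input as unrooted.

# The eight distances

**Robinson–Foulds** counts splits present in exactly one tree.  It is
integer-valued, cheap, and saturates easily: the benchmark below measures
how often uniformly random tree pairs attain its maximum 2(n − 3).

**Information-theoretic distances** (clustering information, CID;
phylogenetic information, PID) refine RF by (i) weighting splits by how
much they say and (ii) giving partial credit to similar-but-unequal
splits.  Both score a pair of trees as

D = H(T1) + H(T2) − 2·M*,

with H(T) the summed information of T's nontrivial splits and M* the
maximum total shared information over one-to-one pairings of splits,
found by an exact Hungarian assignment (`src/assignment.cpp`; validated
in-tree against brute-force enumeration over all pairings).  Unmatched
splits therefore contribute their full information to D.

For CID, a split S = A|B on n leaves carries h(S) = n·H2(|A|/n) bits,
where H2 is the binary entropy, and two splits share n times the mutual
information of their 2×2 joint leaf-membership table.  The n· scaling
(total bits rather than per-leaf bits) is a reporting convention; any
uniform rescaling leaves ranks, correlations, clusterings and mappings
unchanged.

For PID, h(S) = −log2 of the fraction of binary topologies containing S,
i.e. log2(2n−5)!! − log2(2a−3)!! − log2(2b−3)!!.  Two compatible splits
share h(S1) + h(S2) − h(S1 ∧ S2), where h(S1 ∧ S2) derives from an exact
count of topologies containing both: orienting the pair so that one side
A2 nests inside a side A1 (always possible for compatible splits), with
c = |A1| − |A2| and B = the complement of A1, that count is
(2|A2|−3)!!·(2|B|−3)!!·(2c−1)!!.  The test suite validates this closed
form against exhaustive topology enumeration for n ≤ 8; incompatible
pairs share nothing.  Logs of double factorials are computed via
`lgamma`, exact to ~1e−15 — the reason information-distance tests use a
1e−9 tolerance rather than exact equality.

The matching-split information distance is declared (`"ms"`) but raises a
"not implemented" error: no authoritative statement of its pair-scoring
rule was available to implement against, and a guessed scoring would be
worse than an explicit refusal.

**Quartet distance**: for every 4-leaf subset the induced relationship is
one of three resolutions or unresolved; the distance counts subsets whose
status differs, including resolved-versus-unresolved.  The shipped
implementation assigns statuses by the four-point condition on unit-length
path distances (for any tree, the two sums crossing the true quartet are
equal and strictly larger); the tests compare it against an independent
split-containment enumeration.  The O(n⁴) subset loop is vectorised and
adequate for the tree sizes this package targets (n ≲ 50); sub-O(n⁴)
algorithms are out of scope.

**Vector distances** are Euclidean norms of differences of per-leaf-pair
vectors in a canonical pair order (lexicographic by sorted label pair):
path (edges between the leaves, unrooted), KC at λ = 0 (edges from the
root to the pair's MRCA; the pendant-edge block of the original KC vector
is constant at λ = 0 and omitted, as it cancels in differences), and the
split size vector, e_ij = size of the smallest nontrivial split side
containing both leaves.  Where no nontrivial side contains the pair,
e_ij := n, the size of the only trivially valid covering set; this keeps
the vector total and the metric well defined.  Only nontrivial splits
enter the SV vector — with trivial splits admitted, every pair would be
covered by a side of size n − 1 and the metric would collapse toward a
constant; the convention here reproduces the worked values
SV((ab)(cd) vs (ac)(bd)) = 4 and vector (2, 4, 4, 4, 4, 2).

Distances are stored as doubles; RF and quartet values are exact
integers.  `distance_matrix()` computes per-tree decompositions once,
checks leaf-set identity across all trees, and can deduplicate identical
topologies first, recording multiplicities so the full multiset is
recoverable.

# Clustering

Four methods, chosen to span centroid, medoid, hierarchical and graph
views of the same distance matrix:

* K-means (Hartigan–Wong, 3 random starts, at most 42 iterations) on the
  rows of the distance matrix as feature vectors — replicating the common
  usage of passing a distance matrix to a coordinate-based algorithm
  without inventing an embedding;
* PAM on the distances directly (random starts and the FastPAM shortcuts
  where the installed `cluster` version provides them);
* hierarchical agglomeration under minimax linkage: each merge minimises
  the radius of the smallest ball, centred on a member prototype,
  covering the union; ties broken lexicographically; cut at k;
* spectral clustering: Gaussian affinity exp(−d²/σ²) with σ = the median
  off-diagonal distance, normalized graph Laplacian, the k smallest
  eigenvectors row-normalised, then PAM in that eigenspace.  The affinity
  kernel is a documented stand-in: spectral pipelines require one and the
  literature this package follows does not specify it.

The silhouette coefficient drives model selection: s(i) =
(b − a)/max(a, b) with a the mean within-cluster distance and b the
smallest mean distance to another cluster; singletons score 0, and so
does the degenerate a = b = 0 case.  `best_clustering()` scans every
(method, k) pair — default k from 2 to min(10, n − 1), a range wide
enough for the tree sets this package targets while keeping the scan
cheap — and returns the maximum-silhouette clustering, breaking ties
toward the smallest k and then the earlier method in the caller's
preference order.  Coefficients above 0.7/0.5/0.25 are labelled
strong/reasonable/weak; below 0.5 the result additionally carries a
`single_cluster` flag, since sub-"reasonable" structure is best reported
as no structure.  Clusterings are compared by variation of information,
VI = H(C1) + H(C2) − 2I(C1;C2) in bits — a metric on partitions, zero
exactly at identity.

# Mappings

`pcoa()` double-centres the squared distances and eigendecomposes.  Tree
metrics are generally not Euclidean-embeddable; when the spectrum dips
below −1e−8 (relative), the Cailliez additive constant is applied to all
off-diagonal distances and recorded (`correction`,
`params$additive_constant`).  Cailliez rather than Lingoes because the
additive-constant form is the standard practice this package mirrors.
Axes are ordered by non-increasing eigenvalue, so "the first k axes" is
well defined for the diagnostics; degenerate spectra are padded with zero
coordinates to the requested dimension.

`map_space()` adds six methods.  All iterative ones (Kruskal-1, Sammon,
CCA, t-SNE) start from the PCoA configuration — the literature is silent
on initialisation, and a deterministic start makes runs reproducible and
mutually comparable — and record their final stress or objective:

* Kruskal-1 (`MASS::isoMDS`) and Sammon (`MASS::sammon`): stop at
  relative stress change < 1e−6 or 500 iterations.  Both reject zero
  dissimilarities, so duplicate topologies are separated by a tiny
  epsilon (1e−3 × the smallest positive distance) and coincident initial
  points are jittered by 1e−8 under the caller's seed.
* CCA: online updates that preserve distances short *in the mapping*,
  with the neighbourhood radius shrinking geometrically from the 90th to
  the 10th percentile of the initial mapped distances over 50 epochs and
  a linearly decaying step size from 0.5.
* Diffusion map: Gaussian kernel with ε = 2·median(d)², Markov
  normalisation, coordinates = leading nontrivial right eigenvectors
  scaled by their eigenvalues.
* Laplacian eigenmap: symmetrised unweighted k-nearest-neighbour graph
  (k = 50, clipped to n − 1), smallest nontrivial eigenvectors of the
  normalized Laplacian.
* t-SNE (exact, O(n²) per iteration): perplexity 30 (clipped to
  (n − 1)/3), 1000 iterations, learning rate 100 with adaptive gains,
  early exaggeration 4 for the first 100 iterations, momentum 0.5
  switching to 0.8 at iteration 250, initialised from the PCoA
  configuration rescaled to sd 1e−4.  The gentler classic schedule is
  used because aggressive exaggeration/learning-rate combinations can
  scatter small tree sets before attractive forces act at this package's
  problem sizes; perplexity and the iteration budget are the parameters
  worth varying on real data.

Eigenvector-based methods fix signs so the largest-magnitude loading is
positive, making every method exactly reproducible from (input, method,
params, seed).

# Distortion diagnostics

Trustworthiness T(k) penalises points that intrude into a mapped
k-neighbourhood without being true neighbours, weighted by their
original-space rank excess; continuity C(k) symmetrically penalises true
neighbours expelled from the mapped neighbourhood.  Both use the standard
normalisation 2/(nk(2n − 3k − 1)) and k = 10 by default (k < n/2
required); neighbour ranks break ties by item index so results do not
depend on sort internals.  The in-repo brute-force rank-list
implementation is the authority the shipped version is tested against.
T·C is the composite score; mappings with both values above 0.95 are
flagged adequate.

Shepard correlations are computed over all C(n, 2) pairs: Pearson r² (1
when the ratio of any two distances is preserved — scale-free) and
Kendall τ (1 when pair rankings agree; the tau-b form, so heavily tied
integer metrics are handled).  Constant mapped distances return r² = 0
with a `degenerate` flag.

The MST extension factor is the mapped length of the minimum spanning
tree computed from *original* distances divided by the length of the MST
computed from mapped distances; the denominator is optimal, so the ratio
is ≥ 1 and equals 1 exactly for distance-preserving embeddings.  Prim's
algorithm with lexicographic tie-breaking makes the edge set
deterministic.

The correlation dimension estimates intrinsic dimensionality as the
log–log slope of the pair-correlation sum C(r) = 2/(n(n−1))·#{pairs with
d ≤ r}.  The fit uses 25 log-spaced radii between the 0.5% and 10%
quantiles of the positive off-diagonal distances.  The window matters: at
large radii C(r) saturates toward 1 and the local slope falls below the
true dimension (closed form for points uniform on a segment: the slope
drops from ~0.92 at the lower quartile of pair distances to ~0.75 at the
upper, so a quartile-based fit reads ~0.84 for a genuinely
one-dimensional set).  The small-radius window recovers ~0.98 for a
segment and ~1.87 for a square — the package's tests assert 1.0 ± 0.15
and 2.0 ± 0.25 on 500-point clouds.  The window actually used is
returned with the estimate; a zero-variance distance matrix returns
dimension 0 with a `degenerate` flag.

`axis_covariate_r2()` regresses a covariate (typically stratigraphic
congruence) on axis prefixes 1..k and reports adjusted r²,
1 − (1 − R²)(n − 1)/(n − k − 1); it is fit on all trees rather than
cluster representatives, the simpler and more transparent default.

# Stratigraphic congruence

`minimum_implied_gap()` dates every internal node of a rooted cladogram
at the oldest first-appearance date (FAD, Ma) among its leaf descendants
— the assignment that minimises total implied gap, which the tests verify
numerically by perturbing node dates — and sums parent-minus-child date
differences over all edges.  The root's subtending edge contributes
nothing (no origin time is assumed), last-appearance dates never enter
the statistic, and dates are carried as Ma before present (larger =
older).  MIG = 0 exactly when every parent date equals each child's
date, which forces all FADs equal; any non-constant stratigraphy
therefore implies a strictly positive MIG on every topology.

`simulate_stratigraphy()` builds ranges congruent with a reference tree:
internal nodes sit `depth_scale` My per edge below the root (default 5
My, a plausible per-branch duration for the invertebrate and vertebrate
fossil records this kind of analysis serves), each leaf's lineage
originates at its parent's time, and an absolute Gaussian error of scale
`noise` My pulls first appearances toward the present (truncated at 0).
Because FADs track the reference's node order, the reference attains a
near-minimal MIG — not the strict minimum, since a local rearrangement
can occasionally shave an implied gap — and MIG rises with NNI distance
from the reference, which is the property the fixture exists to provide.

# Synthetic fixtures: what they do and do not show

`random_tree()` draws uniformly from all labelled binary topologies
((2n−5)!! unrooted, (2n−3)!! rooted) by inserting each leaf onto a
uniformly chosen edge; the tests verify exact coverage and chi-square
uniformity against complete enumerations at n = 5 and 6.
`simulate_tree_clusters()` derives cluster members from reference
topologies by random NNI moves — local, cheap, and magnitude-controlled
by the move count; n_moves = 0 gives within-cluster distance 0 under
every metric.  `subsample_posterior()` is deterministic: drop the first
⌊burn-in·N⌋ trees, take the target count at uniform intervals.

These generators emulate the *geometry* a practitioner meets — tight or
overlapping clusters, posterior-like streams, stratigraphically ordered
ranges — but not the processes behind real data: no character evolution,
no model misspecification, no correlation between topology frequency and
data quality, and NNI perturbation explores tree space more locally than
MCMC or parsimony searches do.  Passing tests on these fixtures shows the
machinery is correct and the diagnostics behave as their definitions
demand; it does not certify how any particular empirical tree space will
look.

# Benchmark conditions

`balance_independence()` draws pairs of rooted binary topologies
uniformly (default 10,000 pairs of 25-leaf trees), computes each metric
on the identical topological sample — unrooted copies for the unrooted
metrics, TCI always from the rooted form — and reports the squared
Pearson correlation between the distance and |ΔTCI|.  The absolute TCI
difference is used because a signed difference has arbitrary sign for an
unordered pair.  `saturation_test()` draws unrooted pairs (default
100,000 of 11-leaf trees; unrooted, consistently with the RF maximum
2(n − 3) = 16) and counts pairs at the per-pair maximum — 2(n − 3) for
RF, C(n, 4) for quartets, H(T1) + H(T2) for the information distances,
within 1e−9 relative tolerance for real-valued metrics.  Metrics without
a defined attainable maximum (path, KC, SV) are refused.

The test suite and `scripts/acceptance.R` run these at their full stated
sizes; unit tests elsewhere use hundreds of pairs, a size chosen to
exercise every code path while keeping the default suite quick.

# Known limitations

* Quartet distances are O(n⁴); information distances solve an O(k³)
  assignment per pair.  Both are comfortable at the sizes the package
  targets (tens of leaves, thousands of trees after deduplication) but
  are not engineered for hundreds of leaves.
* The matching-split information distance is declared but unscored.
* t-SNE and CCA hyperparameters are documented stand-ins; on real data
  the perplexity and the neighbourhood schedule deserve exploration.
* MIG takes FADs at face value; uncertainty in converting occurrence
  data to first appearances is the caller's problem, and rooting is the
  caller's responsibility.
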