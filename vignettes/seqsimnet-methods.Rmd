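---
title: "Methods: similarity networks, minimum-span clustering and centrality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity networks, minimum-span clustering and centrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqsimnet)
```

## The model

A protein family network is defined entirely by pairwise alignment
E-values. For sequences $i, j$ with directed E-values $E_{ij}$ and
$E_{ji}$, the symmetrized sequence distance is the geometric mean

$$d_{ij} = \sqrt{E_{ij}\,E_{ji}},$$

a dimensionless quantity that can span from exactly $0$ (statistically
indistinguishable sequences) to $\sim 10$ (the conventional search
ceiling). Profile-based (iterative) search E-values go through the same
symmetrization and simply carry a different provenance tag; the engine that
produces them is external to this package.

Three modelling assumptions matter:

1. **Missing directions are capped, not dropped.** All-vs-all searches
   routinely report only one direction of a weak pair. `symmetrize()`
   substitutes `e_cap` (default 10) for the missing direction: unreported
   similarity is read as "no better than the reporting ceiling". This keeps
   the matrix total and is conservative — a pair with one strong and one
   missing direction lands at $\sqrt{E \cdot 10}$, far from the strong
   regime. The cap is configurable per call and in the pipeline config.
2. **Exact zeros are preserved.** Zero-distance pairs define conservative
   cores — maximal subsets of a cluster with all pairwise distances
   exactly 0 — so distances are never floored to machine epsilon.
3. **Queries are scored against the fixed base set.** Adding a query to the
   search database perturbs every E-value slightly; the `nrmsd()`
   diagnostic, $\mathrm{NRMSD} = \sqrt{\tfrac1n \sum_i (1 -
   d_i^{b}/d_i^{b+q})^2}$, quantifies that perturbation and justifies the
   fixed-base approximation when it is small. Pairs with $d^{b} = d^{b+q}
   = 0$ contribute zero; a zero denominator against a nonzero numerator is
   an undefined ratio and errors rather than silently saturating.

## Minimum-span clustering

The clustering step is deliberately parameter-free. In one pass, every unit
is linked to its nearest neighbor (distance ties resolve to the
lexicographically smallest id, compared in the C locale) and clusters are
the connected components of the undirected link graph. Because every unit
links somewhere, each cluster has at least two members whenever two or more
units exist, so the cluster count at least halves per level and the
recursion terminates without a scale parameter.

The hierarchy recursion treats level-$k$ clusters as units, with
single-linkage superdistances (minimum cross-pair distance, the length of
the shortest connecting edge). Each cluster-unit is named by its
lexicographically smallest member so that higher-level tie-breaks remain
deterministic. Level $k+1$ clusters are exact unions of level-$k$ clusters
by construction; the recursion stops at `max_levels` (default 3, read as
sequences → clusters → families) or when one cluster remains.

Two consequences of this construction are worth stating plainly:

- **A singleton group can never survive a level.** Its unit must link to
  *some* nearest neighbor, so a cluster that is "alone" at scale $k$ merges
  with its nearest group rather than persisting. Planted benchmark
  hierarchies therefore give every group at least two children when exact
  recovery is the property under test.
- **The algorithmic detail is this package's choice.** The published
  descriptions of minimum-span clustering that motivated this design state
  its properties (hierarchical, no hyper-parameters, no preset cluster
  count) rather than an algorithm; the nearest-neighbor-link recursion here
  satisfies all of them and is flagged as a reimplementation choice, not a
  reproduction of a reference code path.
- **Raw MSC levels and annotation-based grouping are kept separate.**
  `build_hierarchy()` reports what the distances imply;
  `annotate_partition()`/`name_clusters()` report majority family labels on
  top. The package never corrects one by the other, because how (or
  whether) to mix them is a curation decision, not an algorithmic one.

Cluster naming follows the field's convention: a 2-3 character family
prefix plus a 3-digit rank, largest cluster first (`Pe001` is the largest
peptide receptor cluster). All ties everywhere — nearest neighbors, MST
edges, label majorities, numbering — break lexicographically, so repeated
runs and platforms produce identical output.

Minimum spanning trees use Kruskal's algorithm over all pairs; equal
distances prefer the edge whose (smaller id, larger id) pair sorts first.
Core extraction reduces each zero-distance component to a clique by
greedily removing the member with the most nonzero in-component pairs
(ties remove the lexicographically largest). Exact maximum-clique search is
NP-hard and unjustified here: observed cores are near-cliques already, and
the greedy reduction is deterministic.

## The weight transform and centrality

E-value distances are numerically unusable as edge lengths (150+ orders of
magnitude), so the network layer works with

$$\tilde d_{uv} = d_{uv}^{\,q} + \delta, \qquad
  w_{uv} = \frac{1}{\tilde d_{uv} + 1},$$

with defaults $q = 0.01$ and $\delta = 10^{-200}$, and $0^q \equiv 0$. The
exponent compresses $d = 10^{-100}$ to $\tilde d \approx 0.1$; the offset
keeps transformed distances strictly positive so zero-distance pairs carry
a finite, maximal weight just below 1. Diagonals of both matrices are 0.
Weights are strictly decreasing in distance and live in $(0, 1]$.

- **Closeness** uses shortest *path* distances over $\tilde d$ (single
  source shortest paths via igraph), not the matrix entries: transformed
  E-value distances routinely violate the triangle inequality, so a
  two-hop route can genuinely be shorter than the direct edge. On
  disconnected graphs the $(|V|-1)/\sum \tilde d$ formula applies per
  component with $|V|$ the component size; isolated nodes get 0. No
  cross-component distance is ever defined.
- **Betweenness** (node and edge) sums, over unordered pairs $j < k$, the
  fraction of shortest $j$-$k$ paths through the node (endpoints excluded)
  or edge (endpoint pairs included — the direct edge carries its own
  pair). Two path lengths count as tied when
  $|L_1 - L_2| \le 10^{-12}\max(L_1, L_2)$; the tolerance absorbs float
  accumulation over $\delta$-scale edges and is configurable (`tol`).
  Path counts are accumulated on a predecessor DAG ordered by distance
  from the source; nodes at *exactly* equal distance (possible when a
  $\delta$-scale edge underflows a path sum) are ordered by processing
  position, which keeps the count acyclic and deterministic.
- **Eigenvector centrality** is the leading eigenpair of $W$ by power
  iteration from the uniform vector, converged when successive iterates
  differ by less than `tol` (default $10^{-12}$, cap 10 000 iterations,
  non-convergence is an error that reports the iteration count). The
  iteration actually runs on $W + I$: the shift leaves eigenvectors
  untouched but breaks the $\pm\lambda$ oscillation of bipartite weight
  patterns (a star graph never converges under plain power iteration).
  The returned vector is nonnegative with unit Euclidean norm. A
  disconnected graph violates the uniqueness precondition; the computation
  then proceeds per component (warning), each component's subvector unit
  norm, and $\lambda$ is the maximum component eigenvalue.
- **Thresholded views** keep edges with $d \le t$ (all nodes retained) and
  recompute every measure on the thresholded graph, matching the visual
  semantics of a pruned network; `recompute = FALSE` exposes the
  alternative reading (full-graph centralities, filtered edge list). The
  default family-view threshold is $10^{-100}$, and the pipeline's default
  view list is $\{10^{-20}, 10^{-50}, 10^{-80}, 10^{-100}\}$. The MST
  centrality graph computes all measures *on the tree*.

A planted zero-distance core makes its members exchangeable (identical
distance rows), so core members receive identical closeness and
eigenvector centrality to within $10^{-12}$ — weighted degree and
betweenness still discriminate, which is exactly why hub members of a core
stand out in those two measures.

## Classification

A query is a member iff $d_{\min} < \tau$, strictly, with $\tau = 0.0009$
by default — the operating point that maximizes the F-measure of family
identification on the reference base set this method was developed
against. Equality at $\tau$ is deliberately non-member: the boundary is
unaddressed by the decision rule's two printed branches ($d < \tau$,
$d > \tau$), and the conservative branch avoids silently admitting
borderline queries. Members inherit the cluster label of the nearest base
sequence (distance ties → lexicographically smallest base id).

The remote-homology fallback is a pluggable provider rather than a
dependency on any search binary: any function mapping a query id to a
distance vector works, with a precomputed table being the offline case.
`remotely_related = (d'_{\min} < \tau)` qualifies a non-member; it never
flips the verdict, so downstream counts treat remote relationships as
annotations on negatives, not reclassifications. Provider failures are
recorded in the result and leave the verdict unchanged.

Evaluation: `roc_curve()` ranks by $-d_{\min}$, moves tied scores
together (so the trapezoidal AUC equals the Mann-Whitney pair statistic
with half credit for ties), and `optimal_threshold_fmeasure()` sweeps
candidate thresholds placed at *geometric* means of consecutive distinct
$d_{\min}$ values plus one a decade above the maximum — arithmetic
midpoints would be dominated by the larger value on log-scale data. A zero
lower value is floored at $10^{-300}$ inside the mean so the candidate
stays strictly between the two observations. F-measure is read as $F_1$
(the harmonic mean); ties in $F$ prefer the smallest threshold.

## What the synthetic generators emulate — and what they do not

`planted_cluster_matrix()` draws log-uniform distances within the band of
the deepest level at which a pair shares a group, with bands strictly
separated across levels. Within every group, one member (cluster) acts as
a hub whose pairs come from the lower half of the band while the rest use
the upper half. This hub-and-spoke profile mirrors the highly connected
hub sequences seen in real families and makes nearest-neighbor linkage
provably keep each planted group connected — with purely uniform draws a
cluster of four can split into two mutual-nearest-neighbor pairs, which is
a property of the sampler, not of the clustering. Zero-core members share
identical distance rows (zero distance means effectively identical
sequences), which is also what produces the equal-closeness/
equal-eigenvector core behavior above.

What the generator does *not* model: realistic E-value distributions
(Karlin-Altschul statistics), length- and composition-dependent score
effects, asymmetric database-size effects, overlapping families, or
annotation noise. Passing the planted-recovery and separability tests
therefore demonstrates algorithmic correctness under clean, margin-
separated conditions — the surrogate for a well-curated base set — not
robustness to the messiness of raw search output against live databases.

`planted_classification_set()` places positive $d_{\min}$ log-uniformly
over ten decades up to `pos_max` ($10^{-4}$) and negatives in
[`neg_min`, 10] ($10^{-2}$), a cleanly separated member/non-member panel;
AUC 1.0 and $F^\* = 1$ on these sets are the expected desk-scale mirror of
a well-separated family boundary, not an empirical claim about any real
query panel.

## Numerical choices and degenerate inputs

| Quantity | Choice | Why |
|---|---|---|
| shortest-path tie tolerance | $10^{-12}$ relative | float accumulation over $\delta$-scale edges |
| power-iteration tolerance / cap | $10^{-12}$ / 10 000 | unit-norm iterates; error on non-convergence |
| duplicate search hits | collapse to minimum E-value | best hit is the standard pair summary |
| serialization | `%.17g` doubles everywhere | E-values span >150 decades; round-trip exactness |
| id ordering | C-locale radix sort | locale-independent tie-breaks |
| single unit | 1-level hierarchy, empty MST, centralities 0 | all operations total |
| all-zero weights | $\lambda = 0$, centralities 0 | no spurious convergence failure |

GraphML and Cytoscape-JSON exports round-trip losslessly; integer
attribute columns are canonicalized to doubles because JSON cannot
preserve the integer/double distinction for integral values. Edge roles
(`core-shortest`, `toward-core`, `tree`, `plain`) encode arrow semantics
as attributes since the exported formats carry no arrowheads.

## Problem sizes used by the test suite

The validation suite checks exhaustively wherever exhaustive is feasible:
closeness/betweenness against full path enumeration on 200 seeded
connected graphs with up to 6 nodes; eigenvector centrality against a
dense eigensolver; MST weights against complete spanning-tree enumeration
(Prüfer sequences, up to $7^5$ trees per instance) on 100 seeded matrices;
hierarchy recovery on 50 planted specs of 9-12 sequences; classifier
behavior on 20 planted 100-query panels. These sizes make enumeration
oracles exact and keep the full suite under a minute; the algorithms
themselves have no small-size assumptions.

## Known limitations

- MSC here is a faithful implementation of the nearest-neighbor-link
  recursion, not of any reference clustering code; on data where the two
  differ, cluster censuses will differ.
- Betweenness is exact ($O(n^3)$ pair sweep); no approximate variant is
  provided for very large graphs.
- The package neither runs alignment searches nor parses their XML/pairwise
  output; it consumes tabular E-values.
- Cross-component closeness is defined as 0 rather than via any reachability
  convention; comparisons across differently-connected thresholded views
  should use the per-component values with that in mind.
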