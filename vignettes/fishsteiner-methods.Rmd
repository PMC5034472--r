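---
title: "Steiner-tree models of tumor progression from FISH copy numbers"
author: "fishsteiner"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steiner-tree models of tumor progression from FISH copy numbers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishsteiner)
```

## The model

Multi-probe FISH assays count the copies of a handful of preselected genes in
hundreds of single cells. Each cell yields a *cell count pattern*
$(x_1,\dots,x_d)$ of non-negative integers, one per probe. Tumor progression
is modeled as a tree over these patterns in which a branch between patterns
$x$ and $y$ costs the number of single-gene duplication and loss events
separating them, i.e. the rectilinear (L1) distance
$\sum_j |x_j - y_j|$. Under this metric:

* **MST** — the minimum spanning tree over the observed patterns alone;
* **RSMT** — the rectilinear Steiner minimum tree, which may add unobserved
  *Steiner* patterns (missing intermediate cell states) to shorten the tree;
* **MPT** — the maximum-parsimony tree: an unrooted binary tree with the $n$
  observed patterns as leaves and $n-2$ labeled internal nodes;
* **DSMT** — the duplication Steiner minimum tree, whose generalized branch
  metric admits unit-cost chromosomal and whole-genome duplications.

A minimum-weight tree explains the sample with the fewest mutation events
from a single ancestor, typically the healthy diploid pattern $(2,\dots,2)$.
RSMT and DSMT are NP-hard, so the package provides two heuristics plus an
exact small-instance solver used as ground truth in the test suite.

## Median insertion from the MST (`msttree`)

For three patterns the optimal Steiner point is the coordinate-wise median:
each probe can be optimized independently, and the integer median minimizes
the summed absolute deviation. The star through the median costs
$\sum_j(\max_j - \min_j)$, and a genuinely new Steiner state is needed
exactly when the median differs from all three inputs.

`msttree()` starts from the L1 MST and repeatedly improves it with median
insertions. Every (center, neighbor-pair) triple of the current tree is a
*median instance*; its *local gain* is the weight of the two center-incident
edges minus the weight of the median star. Because the order of insertions
changes the final weight, candidates are prioritized by the *inference
score*: each node's *Steiner count* is the number of triples containing it
whose median is a new state, and a candidate's score is the sum of the
Steiner counts of its three nodes. At each step the positive-gain candidate
with the lowest score is inserted (ties: larger gain, then smallest median
pattern lexicographically, then smallest node indices), the two
center-incident edges are replaced by the 3-star at the median, and
unobserved nodes of degree ≤ 2 that do not shorten the tree are spliced
out. The weight strictly decreases with every insertion, so the loop
terminates at a local optimum no heavier than the MST.

Design points that the problem statement leaves open, fixed here once:

* every (center, neighbor-pair) combination is scored — this subsumes the
  path and star cases and keeps the candidate set $O(\sum_v \deg(v)^2)$;
* insertion rewires only the two edges of the chosen instance;
* all tie-breaks are deterministic, so runs need no seed.

## Parsimony route (`mpttree`)

Copy numbers are ordered integer characters, so the parsimony score of a
leaf-labeled topology is computed exactly by the classic interval (Wagner)
dynamic program, per probe: a leaf carries the degenerate interval $[x,x]$;
an internal node combines its children's intervals — their intersection at
no cost, or the gap between them at a cost equal to the gap length. The
package implements the DP in C++ with a general $k$-child combination rule
(the middle two of the $2k$ sorted interval endpoints), which makes the
score independent of the rooting chosen for the sweep and lets the same
kernel score rooted, pruned and multifurcating trees. The search is
self-contained — random-addition greedy stepwise insertion followed by
best-improvement NNI (SPR available via `search_config(neighborhood =
"spr")` for small instances) — so no external parsimony program is needed.
The default is 10 random-addition restarts; the first restart always uses
the input order, so `restarts = 1` is fully deterministic.

**Labeling, lifting and contraction.** An MPT topology with optimally
labeled internal nodes becomes an RSMT by contracting *trivial* (zero-
length) branches; every remaining internal node with a label not among the
inputs is a Steiner node. Since many optimal labelings exist, the package
minimizes the number of Steiner nodes at unchanged weight:

1. For each leaf, test whether it can be *lifted*: delete the leaf, root at
   its former parent, force the root label to the leaf's pattern, and check
   that the forced weight equals the parsimony score. The forced weight is
   available from the same bottom-up pass, because outside a subtree's
   Farris interval the optimal cost grows at least linearly — so the cost of
   forcing a root value $v$ is the subtree minimum plus the distance from
   $v$ to each child interval.
2. Each liftable leaf yields a candidate: assign internal labels top-down,
   every node taking the value in its interval closest to its parent's
   value (clamping is optimal for the same convexity reason), then contract
   trivial branches.
3. One fallback candidate roots the unmodified topology next to leaf 1 and
   picks the root value inside the root interval closest to the diploid
   pattern — any interval point is weight-optimal, and the diploid bias
   reflects the healthy-cell ancestor.
4. The candidate with the fewest Steiner nodes wins (ties: weight, then
   provenance string), and its weight always equals the parsimony score —
   this is asserted, not assumed.

One leaf is lifted per candidate; simultaneous multi-leaf lifting is not
explored.

## Duplication events (`dsmttree`)

The generalized branch metric allows, per branch: at most one whole-genome
doubling, at most one doubling per chromosome, then unit single-gene
events. Doublings apply to the pre-event (parent) counts and compose
multiplicatively. With $c$ chromosomes there are at most $2^{c+1}$
duplication sets, so the package minimizes exhaustively over the grammar —
exact and fast for FISH-sized panels. Halving is not an event, so the
metric is directional; unrooted edges take the cheaper orientation. Whether
several sequential whole-genome doublings or interleaved single-gene events
should be allowed is unknowable from the problem statement; the grammar
above is the declared approximation.

`dsmttree()` seeds with the MST under the generalized metric (rooted at the
diploid pattern when observed), flags every branch whose generalized cost
beats its L1 length, removes those branches, re-solves each component as a
plain RSMT over the patterns it contains, and re-inserts the removed
branches between the nodes carrying the original endpoint patterns.
Because split-and-rebuild is not guaranteed to beat every alternative
topology, the plain RSMT heuristic tree is also evaluated under the
generalized metric and the cheaper candidate is returned — duplication
events can then only ever reduce the reported weight.

## Exact solver

Optimal rectilinear Steiner trees can be assumed to have their Steiner
points on the Hanan grid (the Cartesian product of the terminals'
per-probe values). `exact_rsmt()` runs the Dreyfus–Wagner subset dynamic
program over that grid: exponential in the number of terminals, so the
solver refuses instances above `max_terminals = 8` or `max_vertices = 5000`
rather than silently approximating. The test suite additionally verifies the
Hanan restriction against an unrestricted brute force (Steiner points
anywhere in the bounding box) on tiny instances rather than relying on the
classical theorem alone.

## The simulator

`grow_tree()` defines the synthetic study conditions. From a diploid
founder, each round every existing cell buds a daughter with probability
`growth` — that budding probability is the package's concrete reading of a
"tree growth factor"; the generator behind the published simulation regime
is not publicly specified, so these semantics are declared, not inferred.
Each daughter acquires exactly one event drawn from the event distribution:

* defaults: gain 0.5 / loss 0.5; duplication-enabled runs here use
  gain 0.45 / loss 0.45 / chromosomal 0.08 / WGD 0.02;
* `zero_absorbing = TRUE` by default — a gene lost to copy number 0 cannot
  return, reflecting the irreversibility of homozygous loss;
* when chromosomal duplications are enabled without a probe map, probes are
  assigned round-robin, two per chromosome.

Growth stops as soon as the number of distinct patterns lies in the target
range (default 120–150, matching typical per-sample FISH heterogeneity). A
final round that overshoots the upper bound is resampled; if a large
population keeps overshooting, daughters of the final round are accepted
one at a time until the count first enters the range — each daughter adds
at most one distinct pattern, so the range is always reachable. The sample
is byte-identical for a fixed seed and configuration.

What the simulator does *not* emulate: FISH measurement noise, probe
dropout, or unobserved intermediate states. Every pattern on the lineage
tree is emitted, which makes simulated instances friendlier to the MST
heuristic than real tumors (the spanning tree over *all* intermediate
states needs few or no extra Steiner nodes — on gain/loss-only samples the
three heuristics therefore often tie). Passing the simulation-based checks
shows the heuristics respect their invariants and orderings at scale, not
that they reproduce results on noisy clinical data. With single-gene events
only, the lineage tree is itself a feasible Steiner tree, which yields the
testable bound: heuristic weight ≤ true event count.

## Numerical choices and problem sizes

* All weights are integers; comparisons are exact, no tolerances anywhere.
* Determinism: MST edges sort by (length, lexicographic endpoint
  patterns); median insertion breaks ties as described above; all search
  randomness flows from a single integer seed.
* The test suite validates each kernel against an independent oracle at
  sizes where the oracle is exact: 1000 random triples for the median;
  200 random ≤6-leaf instances for the Wagner DP (per-probe exhaustive
  labeling); 200 random ≤6-terminal instances against the exact solver;
  500 small and 100 full-scale (120–150 pattern) simulated samples for the
  iterative and trend properties. At full scale the parsimony search uses
  2 restarts — on these instances the score is insensitive to more, and it
  keeps the suite brisk; the `search_config()` default remains 10.
* The acceptance script (`scripts/acceptance.R`) recomputes the headline
  quantities on 30 full-scale samples plus 30 duplication-enabled samples
  per run, seeded from `--seed`.

## Known limitations

* Both heuristics are local searches: no approximation guarantee beyond
  weight ≤ MST weight (median route) and weight = best found parsimony
  score (MPT route).
* The exact solver's limits restrict it to 4–8 terminals in practice; at
  published sample sizes (120–150 patterns) optima are unavailable, exactly
  the regime where heuristics are the point.
* Ties among equally light RSMTs are resolved deterministically but
  arbitrarily; enumerating all co-optimal solutions is out of scope.
* Bootstrap-style confidence values for inferred trees are not provided.
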