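---
title: "Detecting protein complexes in RA/co-expression weighted PPI networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting protein complexes in RA/co-expression weighted PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nragewpn)
```

## The model

Protein complexes appear in a protein–protein interaction (PPI) graph as
dense, compact subgraphs, but high-throughput interaction screens
produce graphs with substantial false positive and false negative rates.
This package assigns every interaction a confidence weight built from
two statistically independent sources and detects complexes in the
weighted graph with a core–attachment model.

**Topological evidence.** The resource-allocation (RA) index models each
node as spreading a unit of resource equally among its closed
neighborhood $N(\cdot)$ (the node and its neighbors). The support an
edge $ij$ receives is

$$W_{N,ij} \;=\; \sum_{u \in N(i) \cap N(j)} \frac{1}{|N(u)|},
\qquad |N(u)| = \deg(u) + 1 .$$

Because the endpoints of an edge always belong to the closed
intersection, their own terms are counted: a bridge edge with no shared
partner still scores $1/(\deg i + 1) + 1/(\deg j + 1)$ — it carries all
of the resource flow between its two sides — and every edge of a clique
scores exactly 1, which anchors the index on the unit scale. The
alternative reading that sums only over third-party common neighbors
(under which a bridge scores 0) is available via
`include_endpoints = FALSE`; we kept it selectable because the closed
and open conventions rank sparse regions differently, but the closed
reading is the default since it is the one under which the index's
$[0,1]$ range and the bridge-edge interpretation are coherent.

**Expression evidence.** Interacting proteins tend to be co-expressed,
so the Pearson correlation (PCC) of two genes' expression time courses
is used as a biological confidence score. Strictly negative correlation
is treated as evidence *against* a functional interaction and such edges
are removed before anything else; a correlation of exactly zero is kept
(no evidence is not negative evidence). Pairs with a gene missing from
the expression data, or with a constant profile (PCC undefined), are
retained with their expression term set to zero rather than dropped —
the removal rule applies only to observed negative correlation.

**Blending.** The two maps are combined convexly,
$W = \alpha\,W_p + (1-\alpha)\,W_N$, and the blended map is min-max
normalized to $[0,1]$. Only the final map is normalized: both inputs
already live on the unit scale (raw closed-neighborhood RA values can
marginally exceed 1 in configurations with many degree-2 common
partners and are capped at 1 before blending). Pre-normalizing $W_N$
with a min-max rescale was considered and rejected: it ties every
weight to the single strongest edge in the graph, so small complexes
whose RA support is legitimately below the global maximum get deflated
below the detection density floor.

## Detection

A cluster's **weighted density** is the mean pairwise weight
$2m/(|N|(|N|-1))$, with $m$ the sum of induced edge weights; its
**diameter** is the longest shortest path (in unweighted hops) inside
the induced subgraph. Complex cores must satisfy density
$\ge \lambda$ and diameter $\le \delta$.

The core search is greedy and fully deterministic. Seeds are visited in
decreasing weighted-degree order; a candidate core starts as the seed
plus its strongest neighbor and repeatedly absorbs the adjacent node
that maximizes the resulting density, as long as both constraints still
hold. A grown core is kept when it has at least `min_core_size` members;
nodes covered by an accepted core are skipped as future seeds (overlap
between outputs can still arise through expansion). All ties — equal
weighted degree, equal edge weight, equal candidate density — break
lexicographically on protein identifiers, which is what makes runs
bit-reproducible. The greedy search is not exhaustive: a qualifying
subgraph can in principle be missed when its nodes are absorbed into a
denser neighboring core first.

Each core is then expanded with **second-order neighbors**: every node
within two hops of a core member is a candidate attachment and is
accepted when its total edge weight into the core reaches
`attach_ratio` times the core's average internal weighted degree. This
is a weighted form of the classical core–attachment criterion
("connected to at least half of the core"). Candidates are judged
against the *original* core, never against a partially expanded one, so
the expansion is single-round, order-independent, and never chains
outward. Finally, clusters are processed in decreasing size order and a
cluster is dropped when its neighborhood affinity
$|A \cap B|^2 / (|A||B|)$ with an already-kept cluster reaches
`dedup_na`; genuine partial overlaps survive, since shared subunits
between complexes are biologically real.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.3 | blend between expression (`1`) and topology (`0`); detection quality is flat for values around 0.3, and this is the reference configuration |
| `lambda` | 0.7 | density floor for cores (dimensionless, mean pairwise weight) |
| `delta` | 2 | diameter cap in hops; with 2, every pair of core members shares a neighbor or an edge, the classical "compact complex" reading |
| `min_core_size` | 3 | a 2-node cluster's density is just its edge weight, which would make `lambda` a trivial filter |
| `attach_ratio` | 0.5 | attachment needs half the average internal connectivity of the core |
| `dedup_na` | 0.8 | affinity at which two output clusters are redundant |
| `t` | 0.2 | neighborhood-affinity level at which a prediction matches a benchmark complex when scoring |

## Evaluation battery

`score_complexes()` computes, from the overlap counts
$T_{ij} = |R_i \cap P_j|$ between benchmark complexes $R$ (n) and
predictions $P$ (m): Sn, PPV and ACC (their geometric mean); Jaccard
precision/recall/f-measure with a strict match at Jaccard $> 0.5$;
affinity precision⁺/recall⁺/f-measure⁺ with an inclusive match at
$NA \ge t$; MMR (total affinity of the maximum-weight one-to-one
matching divided by n, so redundant predictions cannot double-count);
FRM (fraction of benchmark complexes with a prediction at
$NA \ge 0.25$); SEP (geometric mean of the complex-wise and
cluster-wise averages of the row/column-normalized overlap products);
and the composites F_MMR = MMR + f⁺ and CS = MMR + FRM + SEP + ACC +
f-measure. Every ratio with a zero denominator is 0. The FRM level
0.25 and the SEP margin normalization follow the conventions
established in the complex-prediction evaluation literature, as they
are not fixed by the battery itself; both are configurable.

Two properties worth knowing when interpreting scores: PPV and SEP
reach 1 for a self-match only when the benchmark complexes are pairwise
disjoint (overlapping benchmark entries split the column mass), and
MMR's matching is computed exactly, which the test suite verifies
against an exhaustive dynamic-programming oracle.

## Synthetic data

`generate_synthetic()` emulates the statistical structure the method
assumes: disjoint planted complexes (sizes uniform on `size_range`)
whose internal edges appear with probability `p_in`, a background of
independent noise edges with probability `p_out`, and an expression
time course in which co-members share a latent sinusoidal profile
(three periods over `n_timepoints = 36` points, mimicking a yeast
metabolic-cycle design) mixed with an independent component so that the
latent signal carries a `rho` share of the variance, plus observation
noise. Planted complexes are redrawn until connected with diameter at
most 2, so perfect recovery is well-posed; the defaults (20 complexes,
sizes 4–8, `p_in = 0.95`, `p_out = 0.005`, `rho = 0.8`,
`noise_sd = 0.3`, 40 background proteins) are the reference conditions
used throughout the tests and the acceptance script. `perturb_network()`
adds and removes random edges to emulate screen noise.

What the generator deliberately does **not** emulate: overlapping
complexes, scale-free background topology, missing expression values,
and — most importantly — any statistical coupling between expression
noise and interaction noise. Because the simulated expression signal is
unaffected by network perturbation, co-expression acts as a nearly
clean oracle on these simulations, which real data does not provide.
Consequently, passing recovery tests show the pipeline's machinery is
correct and well-calibrated, not that the blend outperforms
single-source weighting on real screens; on these simulations the
expression-only ablation is at least as accurate under network
perturbation precisely because the perturbation damages only the
topological channel. The second-order-expansion ablation behaves as
intended in the same experiment: expansion re-attaches members whose
core edges were removed, and the suite verifies it never lowers the
affinity-based f-measure⁺ there.

## Numerical choices

- Min-max normalization treats a spread below $10^{-12}$ as degenerate
  (all values set to 1) so floating-point noise among effectively
  identical scores is not amplified to the full unit interval.
- Duplicate input edges collapse to the maximum weight; self-loops are
  dropped with a warning.
- Edges whose final blended weight is 0 are retained in the weighted
  graph: zero confidence is not absence.
- Empty candidate sets, edgeless graphs and empty prediction sets
  short-circuit to empty results or errors as documented per function;
  density is undefined (an error) below 2 members, and diameter of a
  disconnected member set is `Inf`, which can never satisfy the cap.
- All randomness (generator, perturbation) is seeded explicitly;
  detection itself is deterministic.

## Problem sizes

The test suite and the acceptance script run entirely on simulated
data: reference networks of roughly 160 proteins and 300–400 edges
(20 planted complexes plus background), 5 generator seeds for recovery
and 10 for the paired ablations, 100 random graphs of up to 30 nodes
for the RA oracle checks, 1000 random vector pairs for the correlation
checks, and 200 random affinity matrices up to $7 \times 7$ for the
matching oracle. These sizes were chosen so that every experiment is
exactly reproducible in seconds to minutes on a single core; the
algorithms themselves have no scale-dependent switches, and the
detection loop's cost grows with the number of edges and the size of
the discovered cores.

## Known limitations

- The greedy core search trades exhaustiveness for determinism; its
  completeness on small graphs is monitored empirically in the test
  suite as a best-effort property, not guaranteed.
- A node can appear in several output clusters only via expansion, not
  via core membership; methods that resume seeds inside accepted cores
  find more overlapping cores.
- Identifier handling is deliberately dumb: case-sensitive opaque
  strings, no mapping between naming schemes.
- GO-term functional enrichment of predictions is out of scope; it
  requires external annotation resources.

```{r example}
sim <- generate_synthetic(synth_config(n_complexes = 4, seed = 7,
                                       n_background_nodes = 10))
fit <- nrage_wpn(sim$network, sim$expression)
fit
score_complexes(sim$truth, fit$complexes)
```
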