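---
title: "Proximity-based link prediction and gene prioritization on heterogeneous networks"
author: "HetNetProx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proximity-based link prediction and gene prioritization on heterogeneous networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HetNetProx)
```

# The model and its assumptions

HetNetProx treats integrated biological knowledge as a typed graph
*G = (V, E, p)*: nodes are entities (genes, proteins, pathways, articles,
phenotypes, ...), edges are relationships, and *p* maps each edge to a
probability-like weight. Three modelling assumptions matter:

1. **Guilt by association.** Entities that are close in the integrated
   graph tend to be biologically related. Mutations in functionally
   related genes (same pathway, same complex) tend to affect the same
   phenotypes, so graph proximity is predictive of future direct links
   and of shared disease involvement.
2. **Effectively undirected edges with directed types.** Every edge type
   has an inverse (`codes_for` / `coded_by`); each relation is stored once
   in a canonical direction and queried from either side. Parallel edges
   between the same node pair are collapsed, keeping the maximum
   reliability — the strongest evidence for the relation. Self loops are
   rejected; no supported relationship type is reflexive.
3. **Edge weights as probabilities.** The weight
   `p(e) = q(e) · i(e) · r(e)` multiplies a per-type relevance, a
   degree-based informativeness penalty, and the source reliability.
   Probabilistic measures require `min(p(e), 1)`; the random walk
   normalizes transition probabilities per node, so it uses the raw
   product.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.25 | degree-penalty exponent in `deg(u)^-α · deg(v)^-α` (dimensionless, in [0,1]); 0 disables the penalty, 1 penalizes hubs maximally. 0.25 is a moderate penalty that proved robust in preliminary exploration of the original weighting scheme; it can be re-optimized per task. |
| `degreeMode` | linktype_independent | whether the penalty uses total degree or the degree restricted to the edge's own type as seen from each endpoint. |
| relevance `q` | 1 (0.8 for the uniform baseline) | per-edge-type prior importance, in [0, ∞); tuned one type at a time on training pairs. |
| `cap` | TRUE for best-path / reliability / expected reliable distance, FALSE for the random walk | whether weights are clipped into [0,1]. |
| `beta` | 0.2 | restart probability of the random walk, chosen to roughly correspond to the uniform relevance 0.8 of the probabilistic measures (per step, dimensionless). |
| `nSamples` | 10000 | Monte-Carlo realizations for reliability / conditional distance. |
| `rwIterations` | 1e6 | steps of the simulated walk (the exact sparse solve is the default and is preferred at all scales we ship). |
| `maxNodes`, `maxDepth` | 1000, 4 | neighborhood bound for Monte-Carlo measures (see below). |
| `k` | 4 | neighbours in the KNN classifier; suitable when about five true positives are expected among the candidates. |
| `q` (cluster) | task-dependent | sensitivity of the single-cluster classifier; a gene joins the cluster when its average proximity to current members exceeds `q`. Varied over a grid to trace a pseudo-ROC. |
| `restarts` | 100 | greedy restarts of the cluster search; more gave no practical improvement. |

# Numerical choices

* **Two-terminal reliability and the conditional expected distance are
  #P-hard**, so no exact polynomial algorithm exists. We estimate both by
  Monte-Carlo over realizations of a *bounded neighborhood subgraph*
  (default: nodes within 4 hops of either terminal, truncated to the 1000
  nodes with the highest best-path probability to the nearest terminal,
  ties broken by node id). An exhaustive `2^|E|` oracle
  (`exactReliabilityOracle`, at most 20 edges) verifies the estimators in
  the tests. The Monte-Carlo kernels are written in C++ but consume R's
  RNG, so a seed reproduces estimates bit for bit.
* **Best path** is a shortest path under the `-log` transform of the
  weights; zero-weight edges are treated as absent for every measure.
* **The exact random walk** solves `π = β e_s + (1 − β) P' π` by a sparse
  LU factorization per connected component (residual tolerance at
  numerical precision). Because zero-weight edges are dropped first,
  every non-singleton node inside a component has a neighbour, so the
  chain is well defined; an isolated root yields the point mass on
  itself. In the *simulated* walk every step counts as a visit, a restart
  counts as a visit to the root, and a dangling node forces a restart.
  One factorization serves all sources in a component, which is what
  makes scoring hundreds of pairs and building proximity matrices cheap.
* **ROC ties** are processed as a single group (diagonal segment), so the
  trapezoidal AUC equals the Mann-Whitney statistic with ties counted
  1/2 — the convention consistent with AUC's interpretation as the
  probability that a random positive outranks a random negative. The
  paired AUC comparison uses the DeLong covariance of placement values;
  identical score vectors give p = 1 by construction.
* **Degenerate inputs.** A pair with a node absent from the graph scores
  0 with a warning (dropping it silently would bias the AUC; real
  candidate lists contain unindexed entities). The conditional expected
  distance is `NA` when no sampled realization connects the terminals.
  Empty and singleton clusters score 0, and the empty cluster is an
  admissible optimum.
* **Cluster search.** The score sums `p(s,t) − q` over *ordered* pairs,
  twice the unordered sum; this only rescales `q` relative to the
  proximities and leaves cluster rankings unchanged. Greedy moves use
  best improvement with ties broken by the smallest node id; each move
  strictly increases the score, so termination is guaranteed, and any
  terminal state has non-negative score (a negative-score state always
  has a member whose removal improves it).

# Design choices where the design was open

* **Degrees count each undirected relation once** (not once per
  direction): the informativeness formula treats the two endpoints
  symmetrically, and double-counting would merely rescale `alpha`.
* **Leave-one-out negatives** are scored with the *exact* average over
  all size-`|S_P|−1` reference subsets rather than a random rotation —
  the strictest reading of "each subset used equally often". The average
  collapses algebraically to the mean proximity over all of `S_P`
  (each positive appears in all but one subset), which the tests confirm
  against explicit enumeration.
* **Relevance tuning is evaluated under the random walk** (uncapped
  weights). Under capped best-path weights a large relevance saturates
  whole edge classes at probability 1 and the ranking signal collapses
  into ties; the walk renormalizes, so relevances act as intended
  (relative transition preferences). Each type is tuned independently on
  a grid with all others at 1, after pinning the gene–protein link
  relevance at 10; a type is only moved off the default when it improves
  the training AUC by at least 0.002 (operationalizing "no noticeable
  effect"). Because the independent protocol cannot guarantee that the
  combined map helps, a final guard re-evaluates it and falls back to
  the pinned-only map if it underperforms the baseline.
* **Random cluster initialization** includes each candidate independently
  with probability 1/2.
* **The pseudo-ROC is returned as a plain table** `(q, fpr, tpr)` rather
  than as a `RocCurve` object: composite points averaged over cases need
  not be monotone and need not reach (0,0) or (1,1), so the curve class's
  invariants deliberately do not apply.

# What the synthetic generator emulates — and what it does not

The generator builds a graph of about 2000 nodes over 4 node types
(Gene, Protein, Pathway, Article) and 6 edge types. Endpoints of
background edges are chosen with probability proportional to
`(degree + 1)^skew`, reproducing the heavy-tailed degree distributions of
real integrated databases (hub articles and pathway nodes). Curated edge
types carry reliability 1; predicted associations draw reliabilities from
Beta(4, 2), echoing the fact that only predicted links carry sub-unit
confidence scores. Twenty planted families of 8 genes are wired to 2–3
dedicated pathway nodes each (membership probability 0.8), so family
members are proximal through *shared intermediates* rather than direct
edges — prioritization must exploit multi-hop structure, mirroring the
premise that related genes share annotations. Direct within-family
associations are added with probability 0.5 and half of them are moved
out of the visible graph as held-out "future links", emulating the
old-versus-current database split used for honest link-prediction
evaluation; negatives are sampled from the positive-support nodes so they
are equally well-studied.

The generator does **not** reproduce the scale (10^6 nodes), the full
type inventory, literature text, curation biases, or the empirical degree
statistics of real integrated databases beyond qualitative heavy tails.
A green test therefore establishes that the algorithms behave correctly
and that planted signal of realistic shape is recovered — not that any
particular accuracy would be attained on real data.

# Known limitations

* Monte-Carlo reliability on the bounded neighborhood is an approximation
  twice over (sampling + bounding); pairs whose connectivity runs through
  nodes outside the bound are underestimated.
* The relevance-tuning heuristic ignores dependencies between edge types
  by design; it approximates, not solves, the joint optimization.
* The cluster classifier needs several true positives among the
  candidates to be useful; with very few positives the KNN route is more
  robust.
* Genome-wide all-pairs prediction is out of scope: with realistic
  positive rates the false-positive load at any usable threshold is
  prohibitive. The methods assume a pre-enriched candidate set.
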