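---
title: "Children-count-aware GO semantic similarity: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Children-count-aware GO semantic similarity: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gogo)
```

## The model

The Gene Ontology is three rooted DAGs (biological process, molecular
function, cellular component) whose edges are typed child-to-parent
relations, chiefly `is_a`, `part_of` and `regulates`. The similarity of
two terms is computed from the subgraph induced by each term and its
ancestors. Each ancestor `t` of a target `A` receives an S-value: the
maximum, over descending paths from `t` to `A`, of the product of edge
weights — `S_A(A) = 1`, and for any other `t` in the ancestor graph

$$S_A(t) = \max\{\, w_e \cdot S_A(t') : t' \in \mathrm{children}(t) \cap T_A \,\}.$$

Two terms are then compared through their shared ancestors, normalised by
their semantic values $SV(X) = \sum_{t \in T_X} S_X(t)$:

$$S_{GO}(A,B) = \frac{\sum_{t \in T_A \cap T_B}\left(S_A(t) + S_B(t)\right)}{SV(A) + SV(B)}.$$

The Wang baseline uses a fixed weight per relation type (0.8 for `is_a`,
0.6 for `part_of` by the cited convention; configurable, since sources
vary). The children-count-aware measure replaces the constant with

$$w_e = \frac{1}{c + nc(t)} + d,$$

where `nc(t)` is the number of **direct** children of the parent-side
term `t`, counted in the **full** ontology over the configured relation
set, and `d` is the per-relation contribution constant (0.4 / 0.3 / 0.2
for `is_a` / `part_of` / `regulates`). A hub ancestor with dozens of
children then passes on much less contribution than a narrow one — the
qualitative behaviour of information content, with no corpus required.

Two readings of the formula are possible and the package commits to one:

* **`nc` of the parent, in the full graph.** The number of children that
  discounts an edge belongs to the ancestor whose contribution is being
  passed down, and it counts all of that ancestor's children, not only
  those inside the current ancestor graph. Counting inside the ancestor
  graph would erase exactly the effect the measure exists for: a hub with
  28 children outside the query's ancestry would look narrow.
* **`children(t)` within the ancestor graph for the recursion.** The
  recursion's maximum ranges over children that *have* an S-value, which
  only children inside $T_A$ do. This is the only reading under which the
  recursion is well defined.

## Parameters

* `c` (default 0.67): with `d = 0.4` and the minimum `nc = 1`, keeping
  every weight in $(0, 1]$ requires $1/(c+1) + 0.4 \le 1$, i.e.
  $c \ge 0.67$. The default sits at that boundary — the most
  children-sensitive valid setting. Values below 0.67 are refused unless
  an explicit unsafe flag is set, and even then an out-of-range weight
  raises an error at use.
* `d_weights`: 0.4 / 0.3 / 0.2 per relation; dimensionless contribution
  constants inherited from the fixed-weight tradition.
* `relations`: the default measure traverses `is_a` + `part_of`; a
  variant adds `regulates` (its positively/negatively sub-relations are
  collapsed to one type, since a single `d` applies to all three).
* Mixing strategy (default `ABM`): for genes with $m$ and $n$ terms, ABM
  pools row-wise and column-wise best matches and divides by $m+n$. BMA
  (mean of the two directional best-match averages) and BMM (their
  maximum) are also available, as are the grand mean and grand maximum.
  The directional-average forms follow the conventional definitions in
  the mixing-strategy literature; ABM is the $(m+n)$-pooled variant.
  Provable orderings — `Max ≥ BMM ≥ ABM` and `Max ≥ Avg` — are asserted
  on random fixtures in the test suite.
* Affinity propagation: `max_iterations = 500`, `convits = 50`,
  `damping = 0.95`, preference = median. The median is taken over
  **off-diagonal** entries only: the unit self-similarities are not
  "similarities of gene pairs" and would bias the preference upward. The
  diagonal is replaced by the preference, per the standard formulation.
* Noise injection: `round-half-up(fraction × pathway size)` genes
  (0.5 × 10 = 5 exactly), drawn uniformly or restricted to candidates
  whose first two Enzyme Commission levels match a cluster member. In
  EC-matched mode the quota is split across clusters proportionally to
  cluster size, remainder to the largest cluster — the per-cluster
  matching rule is fixed by the protocol, the split is this package's
  choice.

## Information-content baselines

IC is $-\log P(f)$ with $P(f)$ the propagated frequency of `f` — the
annotations falling on `f` or any descendant — using the natural log (any
base rescales Resnik uniformly and cancels in Lin). Propagated counts are
computed by crediting every occurrence to the annotated term and each of
its ancestors once, which is immune to the double-counting that naive
child-sum propagation suffers in a DAG. Totals are per namespace (the
propagated count at the namespace root), so the root's IC is 0 and all
analyses stay within one ontology. Terms absent from the corpus get `NA`
IC, not infinity. Lin similarity with both query ICs zero is defined as
0 — no information, no evidence of similarity. The children-count/IC
analysis groups terms by `nc`, drops groups above `nc = 100` (extreme,
near-zero-IC points), and correlates `log(average IC)` with `nc` —
averaging before logging, the literal reading of the procedure it
follows; groups whose average IC is non-positive cannot be logged and are
dropped with that flagged.

## Numerical and degenerate-input choices

* **S-value ties.** Ties in the recursion's maximum cannot change the
  S-value (they are maxima of equal products); no tie-break policy is
  needed or exposed.
* **MCC.** Any zero factor in the denominator yields 0. The per-gene
  counts always satisfy `TP+TN+FP+FN = n − 1`.
* **AP degeneracy.** Message passing cannot choose an exemplar among
  genes with *identical* similarity profiles; reference implementations
  oscillate or split singletons on such inputs. The package adds jitter
  of magnitude `jitter_scale · (max − min similarity) · 1e-12`, keyed by
  a deterministic hash of the gene-label pair and the seed rather than by
  positional RNG draws: runs are bit-for-bit reproducible, the RNG state
  of the session is untouched, and permuting the input genes permutes the
  partition identically (positional jitter would break that
  equivariance). Jitter of this magnitude breaks exact ties only; it
  cannot rescue inputs with exactly duplicated rows, which are refused by
  no one but simply clustered poorly — the synthetic generator therefore
  never emits annotation-identical genes.
* **AP is approximate.** Message passing maximises net similarity
  heuristically. On balanced, well-separated blocks it attains the
  enumerated optimum (asserted in the tests); on very small unbalanced
  problems with a median preference it can under-cluster, matching the
  reference implementation's behaviour on the same matrices.
* **Non-convergence** returns the current assignment with a warning and
  `converged = FALSE`, never an error.
* **Depth** is the minimum edge count from the namespace root (root = 0),
  and sibling pairs require both members at the requested depth — the
  common convention; the alternative (longest path) is noted as an open
  reading.
* **Cross-namespace edges** (e.g. `part_of` links from molecular function
  into biological process) are kept in the graph, but ancestor traversal
  stops at namespace boundaries by default because similarity is computed
  and reported per ontology; a flag enables cross-namespace traversal for
  users who want it.

## What the synthetic generator emulates — and what it does not

The generator builds a single-root typed DAG per namespace: a configured
number of depth-1 subtrees grown by a two-stage uniform choice (subtree,
then parent within it) so subtrees stay comparably sized, with optional
second parents kept inside the primary subtree to create diamonds. For
clustered genes, each planted cluster owns a depth-1 subtree; its genes
draw each annotation from a small shared core pool of that subtree's
exclusive terms with probability `within_cluster_term_overlap`, and
uniformly otherwise. Clusters share ancestry only at the root, genes in a
cluster share most of a small annotation pool (as pathway members share
most experimental annotations), and no two genes are
annotation-identical. Synthetic EC numbers share their first two levels
within a cluster.

What this does **not** model: the real GO's scale (tens of thousands of
terms), its power-law-ish branching, cross-branch and cross-namespace
links within a query's ancestry, annotation bias toward well-studied
genes, and shallow-corpus effects. A pipeline that recovers planted
clusters here demonstrates that the similarity measure, the clustering
and the evaluation compose correctly and that recovery responds
monotonically to planted signal — not that any particular real pathway
will cluster cleanly.

## Problem sizes

The default fixtures use 60-term ontologies (max depth 5, ~3 depth-1
subtrees), 12 genes in 3 planted clusters with 3–6 annotations each; the
dynamic-programming/enumeration equivalence runs on 500 random DAGs of
5–30 terms; recovery monotonicity averages 10 seeds per overlap level
over the grid {0.2, 0.5, 0.8, 1.0}. These sizes exercise every code path
(multi-parent diamonds, multi-namespace exclusion, noise clusters) while
keeping the whole suite fast enough to run habitually.

## Known limitations

* The worked-example values published for the 2016-09-10 GO release can
  only be checked against that archived release; the corresponding tests
  locate it under `tests/testthat/go-release/` and fail informatively
  when it is absent.
* Only `is_a`, `part_of` and (collapsed) `regulates` relations are
  interpreted; OWL-only constructs and other relations are ignored.
* The supplementary-literature BMA/BMM forms are adopted as the
  conventional directional-average definitions; if a source defines them
  otherwise, the strategy functions are the single place to adjust.
* Affinity propagation with a median preference fixes no cluster count;
  pathological similarity structures (near-constant matrices) can merge
  or split blocks, as the reference implementation does on the same
  inputs.
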