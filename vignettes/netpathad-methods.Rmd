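---
title: "Methods: pathway crosstalk and disease subnetwork inference with netpathad"
author: "netpathad authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway crosstalk and disease subnetwork inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpathad)
```

## The analysis this package implements

Complex diseases such as Alzheimer's disease are driven by many genes of
individually small effect.  Given a curated list of disease-associated
genes, this package asks three questions in sequence:

1. **Which biochemical pathways are over-represented** in the gene list
   (over-representation analysis, ORA)?
2. **How do the enriched pathways relate to each other** through shared
   disease genes (pathway crosstalk)?
3. **How do the disease genes sit inside the protein–protein interaction
   network**, and which additional *linker* proteins knit them into one
   connected module (Steiner subnetwork inference), and is that module
   distinguishable from random (Erdős–Rényi null comparison)?

Every stage is an exported function; `run_pipeline()` composes them with
filter-count bookkeeping.  The package ships a transcription of a curated
enrichment table for "Alzgset" — 430 genes reported associated with
Alzheimer's disease in genetic association studies — as a worked example
whose headline numbers (68 enriched pathways; 41 pathways with six or more
candidate genes; a crosstalk network of 37 pathways and 207 edges) are
recomputed by the test suite and the acceptance script.

## Over-representation analysis

For a query gene set of size $n$ drawn from a universe of $N$ genes, and a
pathway with $K$ members in that universe, the probability of observing $k$
or more pathway members in the query under random sampling is the
hypergeometric upper tail

$$P(X \ge k) \;=\; \sum_{i=k}^{\min(K,n)}
  \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

the one-sided p-value of Fisher's exact test (`hypergeom_tail()`, computed
through `phyper()` and cross-checked in the tests against an independent
binomial-coefficient summation to better than $10^{-10}$ relative error for
all $N \le 60$).  Only over-representation is tested; depletion is not a
question the pipeline asks.

Raw p-values are adjusted with the Benjamini–Hochberg step-up rule across
**all** tested pathways, including those with zero overlap — restricting
the family to pathways that happen to overlap the query would bias the FDR.
The default significance threshold is an adjusted p below 0.05, the
conventional FDR level for enrichment screens.

**Universe choice.**  Web enrichment services each carry their own internal
background, which is why published enrichment p-values are generally not
reproducible from the gene lists alone.  The package default is the union
of all pathway members in the loaded database: self-contained,
conventional, and explicit.  An explicit universe can be passed instead;
query genes outside the universe are dropped with a reported count so the
2×2 table stays coherent.  For the packaged Alzgset table this means the
printed p-values are treated as data (they are validated, not
recomputed): the original background and full pathway memberships are not
available, and the crosstalk stage — which is what the table feeds — needs
only the candidate-gene lists.

## Pathway crosstalk

Two enriched pathways "crosstalk" when they share disease-associated
candidate genes.  The *candidate genes* of a pathway are its members
intersected with the disease gene list; these, not the full memberships,
are the sets $A$ and $B$ scored by

$$\mathrm{JC} = \frac{|A \cap B|}{|A \cup B|}, \qquad
  \mathrm{OC} = \frac{|A \cap B|}{\min(|A|, |B|)},$$

with the edge score their average.  $\mathrm{JC} \le \mathrm{OC}$ always,
so the average is bounded by each; the suite asserts the inequality on
randomized set pairs.

The filter cascade in `build_crosstalk()` is ordered:

1. discard pathways with fewer than `min_genes = 6` candidate genes —
   pathways represented by only a handful of disease genes produce few and
   biased connections;
2. among the survivors, keep pairs sharing at least `min_shared = 2`
   candidate genes;
3. pathways left without any kept pair are not nodes of the network.

Applying the size filter *before* the pair filter is load-bearing: on the
packaged Alzgset table this order yields 41 size-filtered pathways, of
which 37 form 207 crosstalk pairs.  Filtering pairs among all 68 pathways
first would give a different network.

`detect_modules()` partitions the network by Louvain modularity
maximization on score-weighted edges under a fixed seed.  Published module
groupings of crosstalk networks are typically drawn by eye; a community
algorithm is a deterministic approximation offered for orientation, and no
exact module count is treated as a reproduction target.

```{r crosstalk}
tab <- load_alzgset_pathways()
net <- build_crosstalk(tab, min_genes = 6, min_shared = 2)
net
```

## Interactome compilation

Protein–protein interaction sources are merged with set semantics
(`merge_interactomes()`): node set is the union, self-interactions are
dropped, and each unordered pair is stored once regardless of input order
or orientation.  Merging is commutative, associative, and idempotent.
Identifier mapping is deliberately upstream of this package: inputs must
already be gene symbols, because reproducing any particular web mapping
service is not feasible offline and silently remapping would be worse.
Symbols are trimmed and upper-cased at every ingestion point — mixed-case
aliases are endemic in interaction databases — and vertices are stored in
byte-wise lexicographic order, which makes every downstream tie-break
independent of file row order and session locale.

## Steiner subnetwork inference

The biological premise is network parsimony: disease components tend to
communicate along short molecular paths, so the sub-network connecting the
seed genes with the fewest additional proteins is a reasonable estimate of
the disease module.  Finding the minimum Steiner tree is NP-hard;
`steiner_tree()` uses the classical shortest-path heuristic, phrased as
greedy tree merging:

1. every seed present in the searchable graph starts as a singleton tree;
2. the two trees at minimal hop distance are merged through a shortest
   path (Kruskal's rule on the seed metric closure), path-interior nodes
   entering as linkers;
3. the union of merge paths is reduced to a spanning tree and non-seed
   leaves are pruned (a Steiner tree never needs a non-terminal leaf).

Edges are unweighted and path length is hop count: interaction confidence
scores are out of scope and the heuristic's guarantees are cleanest in the
unweighted setting.  On tree-shaped graphs the result is exactly optimal;
in general the node count is at most $2\,\mathrm{opt} - 1$.  The test
suite checks both claims against an exhaustive enumeration oracle on every
labelled connected 4-node graph (all seed sets), every labelled connected
5-node graph (representative seed sets), and random graphs up to 9 nodes.

**Tie-breaking** is total: equal-distance merges are ordered by seed-pair
labels, and an equal-length shortest path is realized by walking from the
smaller endpoint, always stepping to the lexicographically smallest
neighbor that is one hop closer to the target.  Identical inputs therefore
give identical outputs, which the suite asserts under edge-order
permutation.

**Excluded seeds.**  Seeds absent from the graph, and seeds outside the
component holding the most seeds, are reported in `excluded_seeds` rather
than silently dropped; real interactomes are incomplete, so full seed
coverage should never be assumed.

**Densify.**  A bare tree on $v$ nodes has $v - 1$ edges, but the
interactome usually contains many more interactions among the selected
proteins; reported disease modules typically include them.  `densify()`
restores the full induced edge set without changing the node set, and the
pipeline applies it by default (disable with `densify = FALSE`).

## Null model

`generate_gnm()` draws uniform simple graphs with *exactly* the observed
node and edge counts — $G(n,m)$, not $G(n,p)$, because "same number of
vertices and interactions" is an exact constraint, not an expectation.
`compare_to_null()` reports, for each of four topological statistics
(global clustering, mean shortest path on the largest component, largest
component fraction, degree assortativity), the observed value, null mean
and standard deviation, a z-score, and a two-sided empirical p-value
$(r+1)/(R+1)$, where $r$ counts replicates at least as far from the null
mean as the observation.  The add-one rule keeps the p-value away from
zero at finite $R$; its smallest attainable value is $1/(R+1)$.  Which
statistic best captures "non-randomness" is a judgment call, so the
statistic set is configurable and all four are reported by default.

## Synthetic data: what it emulates and what it does not

The generators in this package are first-class, tested code; they define
the study conditions for every statistical claim the suite makes.

* `make_universe(n)` — positional symbols `G000001…`; identical across
  seeds by design, so randomness lives only in the sampling generators.
* `make_pathway_db()` — pathways drawing a fraction `overlap_frac` of
  their members from one common pool and the rest from genes no other
  pathway uses.  Pairwise overlap is therefore a single monotone dial:
  0 gives disjoint pathways (empty crosstalk network), 1 with fixed sizes
  gives identical pathways (JC = OC = 1), and the suite checks that mean
  pairwise JC rises monotonically in between.  Real pathway databases
  have *hierarchical* and heavy-tailed overlap structure that this flat
  pool does not imitate.
* `make_query()` — plants `planted_frac` of the query inside target
  pathways, remainder drawn from the non-target universe.  Power and
  type-I calibration run at 30 of 100 query genes planted into a 50-gene
  pathway within a 2000-gene universe: the planted pathway must be
  flagged in at least 99% of 200 replicates, and a pathway with nothing
  planted (null queries drawn independently of it, via a decoy target) in
  at most 7.5%.
* `make_interactome()` — $G(n,m)$ background (or preferential attachment
  via `model = "pa"` for a heavy-tailed degree distribution) plus planted
  simple paths through fresh low-degree `LNK…` linker nodes.  Planted-path
  recovery is tested on a sparse background (300 nodes, 300 edges, mean
  degree 2) where a planted length-3 chain is almost always the unique
  parsimonious route; at least 90% of planted linkers must be recovered
  across 50 replicates.

Because the default background is $G(n,m)$, synthetic interactomes lack
the heavy-tailed hubs, degree correlations, and ascertainment bias of real
protein networks.  Passing tests therefore demonstrate *algorithmic*
correctness and calibration under controlled conditions — not that any
particular biological subnetwork is recovered from a real interactome.

## Problem sizes, fixtures, and scale

The compiled reference interactome this kind of analysis runs on (16,022
proteins, 228,122 interactions) is a supplementary download and is not
redistributed with the package.  Two scale choices follow:

* the edge-list compilation path is exercised on a *size-matched*
  synthetic interactome (exactly 16,022 nodes and 228,122 edges, with
  injected duplicate, swapped, and self-interaction rows) and must
  recover the exact counts;
* Steiner inference at scale runs on a 4,000-node / 40,000-edge synthetic
  interactome containing all 430 seed symbols, where the result must be a
  valid tree spanning every seed in the largest seed-reachable component
  with seed coverage of at least 0.85.  At mean degree 20 the giant
  component covers essentially all seeds, making the validity and
  coverage contracts sharp while keeping the default test run fast.

The packaged 430-gene seed list is a *synthetic stand-in*: 204 symbols are
real (transcribable from the packaged enrichment table and its
surrounding text), and the remainder are clearly artificial `SYNAD###`
placeholders bringing the list to its documented size.  It exercises
seed-list plumbing and scale-matched benchmarks; it is not a biological
resource, and `load_alzgset_synthetic()` says so.

## Numerical and degenerate-input choices

* Gene symbols: trimmed, upper-cased, deduplicated at every ingestion
  point; empty symbols are errors, not silently dropped.
* All ordering (vertices, edges, tie-breaks, serialized output) is
  byte-wise (`radix`), never locale collation.
* Header auto-detection in gene lists is off by default; a silent
  misparse is worse than an error.
* Empty gene list, empty universe, query fully outside the universe,
  zero seeds in the network, infeasible $G(n,m)$ specs, and malformed
  file lines are all hard errors carrying the offending line number where
  applicable.  An empty *edge file* is a valid empty interactome.
* `hypergeom_tail(0, …) = 1` exactly; BH adjustment on an empty vector is
  an empty vector.
* Empirical p-values use the add-one rule; z-scores are `NA` when the
  null standard deviation is zero rather than infinite.

## Known limitations

* The Steiner heuristic's tie-breaking is principled but arbitrary; a
  different (equally correct) heuristic can return a different tree of
  similar size, so exact node/edge counts of published subnetworks are
  not reproduction targets — validity, coverage, and the approximation
  bound are.
* The printed enrichment p-values of the packaged table depend on an
  external tool's background and full pathway memberships and are
  validated as data, not recomputed.
* Community detection on the crosstalk network is a stand-in for a manual
  grouping; only qualitative structure (several interlinked modules) is
  expected.
* Degree-preserving (configuration-model) nulls are not implemented; the
  $G(n,m)$ ensemble matches size, not degree sequence.
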