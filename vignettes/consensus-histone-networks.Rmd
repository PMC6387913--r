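---
title: "Consensus Bayesian networks of histone-modification patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus Bayesian networks of histone-modification patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoneBN)
```

## The problem

Histone modifications are thought to act combinatorially ("histone code"),
and several marks are known to track alternative splicing. Given binary
presence/absence calls for 38 histone methylations and acetylations over
exons involved in skipping events — split into included vs excluded exons and
their 180 bp flanking intronic regions — this package asks two questions:

1. Which marks co-occur or exclude each other (pairwise structure)?
2. What directed dependency structure relates the marks (network structure),
   and how does that structure differ between splicing classes and regions?

The first is answered with phi coefficients (Pearson correlation on binary
data), the second with score-based Bayesian-network structure learning made
robust by a subsample-consensus protocol.

## Data model

A `ModificationMatrix` is an n x p binary matrix (exons x marks) plus two
dataset-level labels: the region the calls refer to (`exon`,
`preceding_intron`, `succeeding_intron`) and the splicing class (`included`,
`excluded`, `mixed`). Entries must be exactly 0 or 1; rows with no
modification at all are legal but produce a warning, because the upstream
data were filtered to exclude them. The 38 mark names (20 methylations, 18
acetylations) live in `markCatalog()`.

## Pairwise structure: phi coefficients

`pearsonBinary()` computes the Pearson coefficient from the 2x2 contingency
counts; on binary data this is the phi coefficient. A constant column makes
the coefficient undefined and returns `NA` rather than 0 — silently zeroing
would fabricate independence, and downstream consumers (edge coloring) treat
`NA` as "no sign annotation". `correlationMatrix()` computes all pairs via
cross-products and `heatmapExport()` draws the matrix with a diverging
palette centered at 0, ordered either by average-linkage clustering on the
(1 - r) distance (default, exposes the block structure) or in catalog order
(stable across datasets for side-by-side comparison). No p-values are
attached: the analysis uses coefficient signs only, and a significance layer
would suggest precision the binarized data do not support.

## Network structure: score-based search

`hillClimb()` learns a directed acyclic graph by greedy search from the
empty graph over single-edge additions, deletions and reversals, maximizing
a decomposable score:

* **BDeu** (default), the Bayesian Dirichlet equivalent uniform log marginal
  likelihood with equivalent sample size `ess` (default 1 — a weak prior
  that is conservative about adding edges);
* **BIC**, the maximized log-likelihood penalized by `log(n)/2` per free
  parameter.

Search details that matter for reproducibility:

* Moves are accepted only if they improve the score by more than `tol`
  (default 1e-9, below the floating-point noise of count-based scores).
* Ties are broken by a fixed total order — move type (add, delete, reverse),
  then lexicographic parent and child names — so results are identical
  across platforms.
* `maxParents` (default 4) bounds the conditional probability tables at
  2^4 x 2 cells, which n in the 10^4 range estimates comfortably, and
  matches the sparse networks the analysis targets (about 20 edges over 38
  nodes).
* Acyclicity of additions is checked against a cached transitive closure;
  reversals use a per-edge path check.

Greedy single-move search has a well-known failure mode: collider (v-)
structures whose individual edges do not improve the score, so the empty
graph is a local optimum. `LearnConfig(restarts = k)` runs k additional
climbs from seeded random DAGs and keeps the best score; the default is 0
because the consensus protocol (below) already averages over data
perturbations, and a deterministic single climb makes the fold-level results
easiest to audit. The oracle-equivalence benchmark (`scripts/acceptance.R`)
runs hill climbing with 8 seeded restarts for exactly this reason; the
planted-recovery and null-calibration runs use the deterministic default.

`exhaustiveSearch()` enumerates every labeled DAG on up to 4 (optionally 5)
nodes — 543 DAGs on 4 nodes — and returns the score-maximal one. It exists as
an independent oracle: the greedy search can be validated against the true
optimum on small problems. The enumeration itself is validated in the test
suite against the inclusion-exclusion recurrence for labeled DAG counts,
computed independently in the test file.

## The consensus protocol

Single structure-learning runs are unstable: score-equivalent DAGs can swap
edge directions, and marginal edges come and go with the sample. The
protocol implemented by `consensusProtocol()` is:

1. Partition the samples into 10 random folds (`makeFolds()`; sizes differ
   by at most one).
2. Learn one "fundamental" network on each leave-one-fold-out dataset
   (`learnFundamentalNetworks()`), i.e. 10 networks from 90% of the data
   each.
3. Keep the node pairs that appear (in either direction) in at least 7 of
   the 10 fundamental networks (`buildConsensus()`).

Edge identity for the 7-of-10 count is the **skeleton** pair, with direction
resolved afterwards by majority among the networks containing the pair.
Counting directed edges would undercount dependencies whose direction flips
between score-equivalent fold solutions; the strict directed reading remains
available via `edgeIdentity = "directed"`, and both counts are reported per
edge. A direction tie takes the lexicographically smaller node as parent and
is flagged.

Majority directions of individually stable edges can form a directed cycle
even though every fundamental network is acyclic. When that happens, the
lowest-stability edge in each cycle is re-oriented (once) or, failing that,
dropped — always flagged in the output — so the consensus is guaranteed to be
a DAG while losing as little stable structure as possible.

Retained edges are annotated with the sign of the full-dataset correlation
(not per-fold correlations): the final network is colored from the same
correlation matrix the pairwise analysis reports.

One 10-fold round producing 10 fundamental networks is the default. The
protocol description in the source literature can also be read as 10
repetitions of the whole 10-fold procedure; `consensusProtocol(rounds = R)`
implements that reading by pooling R x 10 networks and scaling the threshold
to R x 7.

## Post-analysis

* `findPatterns()` reports the combinatorial patterns of a network,
  operationalized as connected components of size >= 2 of the undirected
  skeleton (a sparse graph's "19 edges, 10 patterns" style summary), plus
  the isolated marks.
* `directMarks()` lists the marks adjacent to a designated outcome node.
  The intended use appends a binary splicing column (1 = included,
  0 = excluded) to the stacked included+excluded matrix of one region
  (`appendOutcomeColumn()`), learns the consensus network over the 39
  nodes, and reads off the outcome's neighbors. This is an explicit
  operationalization: per-class networks contain no splicing variable, so
  "marks directly correlated with splicing" is only well-defined once the
  outcome is a node.
* `diffNetworks()` compares two consensus networks at the skeleton level
  (pairs only in A, only in B, shared, with sign agreement on shared pairs).

## Synthetic data and what the tests show

The original CD4+ T-cell matrices are distributed as third-party
supplementary material, so the package ships a generator instead of data:

* `buildPlantedDag()` draws a random DAG (exact edge count, in-degree cap)
  and attaches noisy-OR-like tables: roots fire at 0.5, children at
  `effect` when any parent is on and `1 - effect` otherwise. One knob
  controls dependence strength; `effect = 0.9` gives strong, clearly
  recoverable edges.
* `forwardSample()` draws rows in topological order; the master seed feeds
  separate topology and sampling streams, so one structure can be re-sampled.
* `histonePreset()` emulates the qualitative correlation geometry reported
  for the real exon data: an H2BK5me1 hub driving H3K4me1, H3K4me2,
  H3K79me1, H3K9me1, H4K20me1 and H4K91ac at effect 0.85, and H3K9me3
  anticorrelated with most other marks. The anticorrelation is induced by a
  shared latent activity state (loading 30 generic marks at 0.45/0.15 —
  marginal 0.3 — and the hub at 0.65/0.35) with H3K9me3 loading negatively
  (0.15/0.45), rather than by 37 explicit edges, keeping the planted graph
  sparse. The 0.3 base rate of generic marks is an invented, documented
  choice; the source data report presence patterns only qualitatively.

What passing tests on these data do show: the learner finds score-optimal
structure on small problems, recovers strong planted dependencies at
realistic n, and the stability filter suppresses noise edges. What they do
not show: performance under the real data's mark frequencies, linkage
between the three regions of one exon (not modeled — the regions are
analyzed separately), or robustness to binarization artifacts upstream of
the matrices.

## Problem sizes and numerical choices

The heavyweight validation runs use the study-scale conditions: 38 nodes,
n = 10^4 rows, 10 folds, threshold 7, five seeds for averaged quantities
(planted recovery, null calibration, outcome recovery), and 100 datasets of
n = 500 for the 4-node oracle benchmark. A single 38-node, n = 10^4 climb
takes on the order of a second; a full consensus run is about ten climbs.

Degenerate inputs are handled explicitly: constant columns give undefined
(not zero) correlations and are excluded from heatmap clustering; all-zero
rows warn once and are otherwise accepted; infeasible planted-edge counts,
fold counts exceeding n, and consensus thresholds outside 1..k are errors
before any computation.

## Reproducibility

Every stochastic step (fold assignment, DAG planting, sampling, restarts)
consumes a stream derived from one master seed, and no package function
perturbs the caller's RNG state. `runPipeline()` writes a manifest with the
canonical config, the seed, and MD5 checksums of every output; rerunning
with the same config and seed reproduces the checksums byte-for-byte,
including the PNG heatmaps.

## Limitations

* Structure learning assumes complete binary data; there is no missing-data
  handling (the upstream matrices have none).
* BDeu/BIC hill climbing is a standard, transparent learner, but it is not
  the (closed-source, discontinued) tool used for the original figures, so
  exact topologies of the published networks are not reproduction targets;
  the protocol, thresholds and summaries are.
* Consensus cycle resolution is a documented invention — any rule that
  guarantees a DAG must make a choice the subsampling itself does not
  determine — and affected edges are always flagged.
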