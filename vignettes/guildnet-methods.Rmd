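---
title: "Methods: network-based disease-gene prioritization in guildnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based disease-gene prioritization in guildnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guildnet)
```

## The problem and its assumptions

Complex disorders are rarely caused by a single gene: the pathophenotype
emerges from perturbations of pathways whose members cooperate through
physical protein–protein interactions. Guilt-by-association prioritization
exploits this: given *seeds* (proteins already known to be associated with
the phenotype) and an interactome, every protein is scored by how well the
network topology connects it to the seeds.

All methods here assume that (i) relevance information can only travel
along edges, so scoring operates on the largest connected component (LCC)
of the network, and (ii) seeds carry more relevance than other nodes,
encoded as two-level initial scores: 1.00 for seeds, 0.01 for non-seeds.
Edge weights are dimensionless interaction confidences, 1 by default;
STRING-style raw confidences in [0,1000] are divided by the fixed score
ceiling 1000 and added to the default, giving weights in [1,2]. Dividing by
the fixed ceiling (rather than min–max over the observed edges) keeps
weights stable when the network is subset; min–max is available as an
option. Interactomes are heavy-tailed: a few hubs touch a large fraction
of the proteome, which is why degree-aware normalization (NetZcore) is part
of the toolbox.

## The four scoring algorithms

**NetShort.** Relevance is proximity to seeds, but distance is itself
phenotype-aware: an edge $(i,j)$ of weight $w$ gets length
$w \cdot 2/(s_i + s_j)$, so a unit-weight edge between two seeds has length
1 while one between two non-seeds has length 100. The score is
$\mathrm{score}(u) = \sum_{v \in S \setminus \{u\}} s_v / d(u, v)$ with
$d$ the Dijkstra distance under those lengths. The prose definition of the
edge function is internally tense — a "product of weight and mean endpoint
score" would make seed-adjacent edges *long*, inverting the stated intent
that seed edges be short — so the package adopts the inverse form above as
the default and keeps the literal product form behind `form = "product"`.
The aggregation (inverse-distance-weighted sum of seed scores) is likewise
a design choice: it is monotone in the stated intuition (shorter seed
distances, higher score) and degrades gracefully with distance.

**NetZcore.** One iteration computes the weight-normalized neighbor
average $\mathrm{raw}(u) = \sum_{v} w(u,v) s(v) / \sum_v w(u,v)$ (a mean,
not a sum, matching the definition as an *average* of neighbor scores) and
replaces each node's score by the z-score of its raw value against the
same statistic computed under each member of a null ensemble. The null
ensemble is 100 degree-preserving permutations: score assignments are
shuffled only among nodes of identical degree, which is equivalent to
rewiring into random networks of identical degree sequence while keeping
the observation fixed. Five iterations propagate the normalized signal.
Two statistical conventions matter and are tested: the ensemble is treated
as the complete reference population (population standard deviation,
denominator $n$), and a node whose null raw score has zero variance gets
z-score 0 rather than a division by zero. Nodes of unique degree (often
the biggest hubs) are fixed points of every permutation; their null
variance then comes only from their neighbors' permuted scores.

**NetScore.** Information travels along shortest paths only, with
multiplicity. Every node starts a repetition holding one message from
itself with path weight 1 (the self-message keeps seeds highly scored
after propagation; it is a package choice, configurable via
`self_message`). Each iteration forwards stored messages to all neighbors,
multiplying the path weight by the edge weight; a receiver accepts
messages from emitter $e$ only in the iteration of first arrival —
exactly the hop-shortest paths, all of them when several tie. After
`max_s = 2` iterations the score becomes the mean over stored messages of
(emitter's repetition-start score × path weight); `nr = 3` repetitions
with message resets extend the horizon to 6 hops without storing the full
$k$-neighborhood. The implementation propagates whole frontier matrices
(path-weight sums and path counts per emitter–receiver pair), which is
algebraically identical to per-message bookkeeping and is validated
against an exhaustive path-enumeration oracle on small graphs.

**NetCombo.** The consensus averages the z-normalized (mean subtracted,
sample standard deviation, denominator $n-1$) score vectors of NetScore,
NetZcore and NetShort. Z-normalization uses the sample convention because
the node set is a sample from the score distribution being standardized,
in contrast to the ensemble case above; both conventions are asserted in
the tests.

**Parameter defaults.** Seed/non-seed initial scores 1.00/0.01, NetZcore
iterations `max_z = 5`, NetScore `max_s = 2` with `nr = 3`, functional
flow `max_f = 5`, and 100 random permutations are the framework's
published operating point (selected there by cross-validated AUC on
held-out text-mining phenotypes); they are defaults, not constants, and
every entry point accepts overrides.

## Baselines

The comparison methods follow their original publications. Random walk
with restart and PageRank with priors iterate
$p \leftarrow (1-r)\,W_{col}\,p + r\,p_0$ on the column-stochastic weighted
adjacency (restart/teleport mass $r$); network propagation iterates
$F \leftarrow \alpha W_{sym} F + (1-\alpha) y$ on the symmetrically
normalized adjacency $D^{-1/2} A D^{-1/2}$; functional flow lets seed
reservoirs of infinite capacity discharge downhill, each edge carrying at
most its weight per iteration and donors spreading at most their reservoir
proportionally to incident edge weights, with a node's score the
accumulated inflow. The mixing defaults (restart 0.75, damping 0.85,
$\alpha$ 0.8) are this package's documented choices. All three walk-type
iterations stop when the L1 change drops below `tol = 1e-6` (cap 100
iterations, an error — never a silent partial result — on
non-convergence); the fixed points are checked against direct linear
solves in the tests.

## Evaluation protocol

Seeds are split into five balanced folds; each fold is held out in turn,
the network is scored from the remaining seeds, and two metrics are
computed. The ROC AUC uses the Mann–Whitney identity (ties count one
half). Because true negatives do not exist for phenotype association,
negatives are synthesized: all non-seeds are shuffled and partitioned into
exactly as many groups as there are held-out positives (sizes
`floor(n/k)` with the remainder spread one per group — every non-seed used
exactly once), and each group's mean score is one negative instance. The
evaluation set is thereby balanced and a symmetric random scorer
calibrates to AUC 0.5, which the acceptance suite verifies by Monte
Carlo. Sensitivity is the fraction of held-out seeds among the top
`ceiling(0.01 · n)` of the ranking; training seeds are excluded from the
ranked list (they are known a priori), ties break by node identifier, and
both choices are configurable arguments.

Seed connectivity is summarized by *Ns* (mean number of seed neighbors
per seed) and *Ss* (mean unweighted shortest-path hop count over seed
pairs; hop counts, not NetShort lengths, because connectivity here
describes the topology, not any method's geometry). Methods are compared
by a one-sided Wilcoxon test, paired over phenotypes, exact for up to 25
informative pairs; performance–connectivity association uses Pearson
correlation by default with Spearman available.

## Synthetic fixtures: what they emulate, and what not

`generate_network()` produces connected scale-free graphs by preferential
attachment (default: 200 nodes, 2 edges per new node), reproducing the one
property of real interactomes these algorithms are sensitive to — a
heavy-tailed degree distribution — plus optional confidence-style weights
uniform in [1,2]. Erdős–Rényi graphs are kept as an alternative because
their large degree classes exercise the degree-preserving randomization
harder. `plant_seeds()` creates the two regimes whose contrast the
evaluation measures: *clustered* seeds are a breadth-first prefix from a
random start (a connected planted module, chosen over random-walk planting
because it deterministically yields exactly `n_seeds` members), *random*
seeds are a uniform sample. Fixtures do not attempt realistic clustering
coefficients, motif spectra, modular community structure, or the false
positive/negative edge noise of real interactomes; a passing planted-module
test therefore shows that the algorithms recover connected modules on
heavy-tailed topology, not that they attain any particular accuracy on a
real proteome. Default sizes (200 nodes, 20 seeds, 20 replicate fixtures
for the recovery checks, 2000 Monte-Carlo replicates for the calibration
check) are chosen so the full suite exercises every method in minutes on a
single core while keeping the replicate-level statistics stable.

## Numerical and degenerate-case choices

- Duplicate edges collapse to the maximum weight on reading (the more
  confident report wins); self-loops are dropped with a warning. Both the
  middle-weight (`node1 weight node2`) and plain (`node1 node2 [weight]`)
  edge-list dialects are supported behind an explicit flag — a
  three-column plain file is ambiguous with the middle-weight layout, so
  auto-detection is deliberately not attempted.
- Equal-sized largest components are resolved toward the component
  containing the lexicographically smallest node identifier, making LCC
  extraction deterministic.
- NetShort refuses `s_i + s_j = 0` (infinite edge length) and
  disconnected inputs, with an error pointing at LCC extraction.
- All stochastic steps (permutation ensembles, fold splits, negative
  grouping, fixture generation) draw from one seeded generator in a
  documented order, so any `rng_seed`-parameterized run is bit-for-bit
  reproducible; `plant_seeds()` offsets the generator seed by one so the
  seed draw does not replay the network draw.
- Score files are written sorted by descending score with identifier
  tie-breaks, and command-layer writers go through a rename-into-place
  temporary file so a failure never leaves partial output.

## Known limitations

The balanced negative-instance construction compares *single* held-out
scores against *group means* of many non-seeds. For strongly right-skewed
score distributions — which centrality-driven scorers such as NetShort
produce on heavy-tailed graphs — a group mean exceeds the typical single
node, so the chance level of the construction sits below 0.5 even for
seed-uninformative rankings. The acceptance suite's scattered-seed check
measures exactly this: with uniformly scattered seeds, NetScore and
NetZcore are statistically indistinguishable from AUC 0.5, while NetShort
(and hence partly NetCombo) falls significantly below it. This is a
property of the evaluation protocol, not of the scorers; comparisons
between methods under the same protocol remain fair, but absolute AUC
values for skew-scoring methods should be read against a Monte-Carlo
chance band rather than against 0.5.

Other limitations: nodes of unique degree have no exchange partners in
the null ensemble; node identifiers are opaque strings (no gene-symbol
mapping); and the dense-matrix NetScore/NetZcore implementations are
comfortable to a few thousand nodes but are not engineered for
proteome-scale networks beyond that.
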