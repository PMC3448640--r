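# guildnet

Genome-wide disease-gene prioritization on protein–protein interaction
networks. Given an interactome and a set of *seeds* — proteins already known
to be associated with a phenotype — `guildnet` scores every node in the
network for phenotype relevance by guilt-by-association, so that candidate
genes can be ranked without restricting attention to any linkage interval.

The package is aimed at computational biologists who have an edge list of
protein interactions (optionally confidence-weighted) and a list of known
disease proteins, and want a ranked list of candidates plus an honest,
cross-validated estimate of how well that ranking works.

## Algorithms

Four network-topology scoring algorithms form the core:

- **NetShort** — a node scores highly when it lies at short weighted
  distance from the seeds, where edges whose endpoints carry high initial
  scores are contracted: an edge `(i,j)` of confidence `w` gets length
  `w · 2/(s_i + s_j)`, and `score(u) = Σ_{v∈S\{u}} s_v / d(u,v)`.
- **NetZcore** — iterative z-score normalization. Each iteration computes
  the weight-averaged neighbor score
  `raw(u) = Σ_v w(u,v)·s(v) / Σ_v w(u,v)` and standardizes it against the
  same quantity under an ensemble of 100 degree-preserving score
  permutations ("random networks with the same topology"), correcting the
  bias of highly connected nodes.
- **NetScore** — message passing restricted to shortest paths. Every node
  emits its score; messages travel one hop per iteration carrying the
  product of edge weights along their path, a receiver keeps only
  first-arriving messages (all tied shortest paths count), and a node's
  score is the mean of (emitter score × path weight) over stored messages.
  Two iterations, repeated three times with score updates in between,
  cover a 6-hop horizon at bounded memory.
- **NetCombo** — the consensus: the mean of the z-normalized NetScore,
  NetZcore and NetShort vectors.

Four global-topology baselines are included for comparison: random walk
with restart, PageRank with priors, network propagation
(`F = (I − αW_sym)^{-1}(1−α)y`), and functional flow. Seeds take initial
score 1.00, non-seeds 0.01.

Evaluation follows a five-fold cross-validation protocol with balanced
pseudo-negatives: the non-seeds are partitioned at random into as many
groups as there are held-out seeds and each group's mean score becomes one
negative instance, which pins the chance-level AUC of a symmetric scorer at
0.5. The package reports ROC AUC (Mann–Whitney form), sensitivity among the
top 1% of the ranking, seed-connectivity statistics (mean neighbor-seed
count *Ns*, mean seed-pair shortest-path distance *Ss*), one-sided Wilcoxon
method comparisons, and performance–connectivity correlations.

A synthetic-fixture module generates connected scale-free (or Erdős–Rényi)
interactomes with planted (clustered) or scattered seed sets and unit or
confidence-style `[1,2]` edge weights, so the entire workflow runs and is
tested without any external data.

## Worked example

```r
library(guildnet)

cfg   <- fixture_config(n_nodes = 200, n_seeds = 20,
                        seed_mode = "clustered", rng_seed = 7)
net   <- generate_network(cfg)          # 200-node scale-free interactome
seeds <- plant_seeds(net, cfg)          # 20-node connected seed module

conn <- seed_connectivity(net, seeds)
sprintf("Ns = %.2f, Ss = %.2f", conn$ns, conn$ss)
#> "Ns = 2.30, Ss = 2.56"

sc <- guild_score(net, seeds, method = "netcombo", rng_seed = 7)
round(head(sort(sc, decreasing = TRUE), 5), 3)
#>  n058  n096  n059  n104  n037
#> 3.402 3.165 2.549 2.348 2.269

cross_validate(net, seeds, method = "netcombo", k = 5, rng_seed = 7)
#> 5-fold cross-validation
#>   AUC:         1.0000 +/- 0.0000
#>   sensitivity: 0.3000 +/- 0.1118 (top of ranking)
```

Each seed here has on average 2.3 seed neighbors and is 2.56 hops from the
other seeds — a tight module — and held-out seeds are ranked above every
negative instance in all five folds (AUC 1.0); 30% of held-out seeds land
within the top 1% (the top 2 of 196 ranked non-training nodes per fold).
With `seed_mode = "random"` the same pipeline drops to chance-level AUC.

A command-line front-end wrapping the same functions is installed at
`system.file("scripts", "guildnet.R", package = "guildnet")` with
subcommands `score`, `evaluate`, `simulate` and `combine`.

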