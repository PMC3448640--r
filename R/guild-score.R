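# Single entry point dispatching to the eight scoring algorithms.

#' Score a network's nodes for phenotype relevance
#'
#' Runs one of the eight prioritization algorithms from a seed set and
#' returns a score for every node. `netcombo` internally runs NetScore,
#' NetZcore and NetShort and averages their z-normalized outputs.
#'
#' @param net connected network
#' @param seeds seed node identifiers (subset of the network's nodes)
#' @param method one of `"netscore"`, `"netzcore"`, `"netshort"`,
#'   `"netcombo"`, `"fflow"`, `"pagerank"`, `"rwr"`, `"netprop"`
#' @param seed_score,nonseed_score initial scores (defaults 1.00 / 0.01)
#' @param max_z NetZcore iterations (default 5)
#' @param max_s,nr NetScore iterations and repetitions (defaults 2 and 3)
#' @param n_random ensemble size for NetZcore (default 100)
#' @param ensemble optional pre-built `guild_ensemble` for NetZcore /
#'   NetCombo (reused across cross-validation folds); built on the fly when
#'   missing
#' @param params [walk_params()] for the walk-based baselines
#' @param max_f functional-flow iterations (default `params$max_f`)
#' @param rng_seed integer seed used when an ensemble must be built
#' @return named numeric score vector over all nodes
#' @export
#' @examples
#' net <- generate_network(fixture_config(n_nodes = 50, n_seeds = 5, rng_seed = 1))
#' seeds <- plant_seeds(net, fixture_config(n_nodes = 50, n_seeds = 5, rng_seed = 1))
#' head(sort(guild_score(net, seeds, "netscore"), decreasing = TRUE))
guild_score <- function(net, seeds,
                        method = c("netscore", "netzcore", "netshort",
                                   "netcombo", "fflow", "pagerank", "rwr",
                                   "netprop"),
                        seed_score = 1.00, nonseed_score = 0.01,
                        max_z = 5, max_s = 2, nr = 3, n_random = 100,
                        ensemble = NULL, params = walk_params(),
                        max_f = params$max_f, rng_seed = NULL) {
  method <- match.arg(method)
  init <- assign_initial_scores(net, seeds, seed_score, nonseed_score)
  need_ens <- method %in% c("netzcore", "netcombo")
  if (need_ens && is.null(ensemble)) {
    ensemble <- degree_preserving_permutations(net, n = n_random,
                                               rng_seed = rng_seed)
  }
  switch(method,
    netshort = netshort(net, init, seeds),
    netzcore = netzcore(net, init, ensemble, max_z = max_z),
    netscore = netscore(net, init, max_s = max_s, nr = nr),
    netcombo = netcombo(list(
      netscore(net, init, max_s = max_s, nr = nr),
      netzcore(net, init, ensemble, max_z = max_z),
      netshort(net, init, seeds)
    )),
    fflow = functional_flow(net, seeds, max_f = max_f),
    pagerank = pagerank_with_priors(net, init, params),
    rwr = random_walk_with_restart(net, init, params),
    netprop = network_propagation(net, init, params)
  )
}
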