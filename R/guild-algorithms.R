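# The four GUILD prioritization algorithms: NetShort, NetZcore, NetScore
# and their consensus NetCombo, plus the degree-preserving score
# randomization that NetZcore requires.

#' Assign two-level initial scores
#'
#' Seeds (nodes known to be phenotype-associated) receive `seed_score`;
#' every other node receives `nonseed_score`. The defaults 1.00 and 0.01
#' are the values found to maximize cross-validated AUC in the framework's
#' parameter optimization.
#'
#' @param net network
#' @param seeds character vector of seed node identifiers, all in `net`
#' @param seed_score initial score of seeds (default 1.00)
#' @param nonseed_score initial score of all other nodes (default 0.01)
#' @return named numeric vector over all nodes
#' @export
assign_initial_scores <- function(net, seeds, seed_score = 1.00,
                                  nonseed_score = 0.01) {
  nodes <- network_nodes(net)
  if (length(seeds) == 0L) stop("empty seed set")
  if (!all(seeds %in% nodes)) {
    stop("seeds not in network: ",
         paste(setdiff(seeds, nodes), collapse = ", "))
  }
  if (!(seed_score > nonseed_score) || nonseed_score < 0) {
    stop("require seed_score > nonseed_score >= 0")
  }
  s <- stats::setNames(rep(nonseed_score, length(nodes)), nodes)
  s[seeds] <- seed_score
  s
}

#' NetShort edge length
#'
#' Length assigned to an edge for NetShort's shortest-path computation:
#' `weight * 2 / (s_i + s_j)`, where `s_i`, `s_j` are the endpoints'
#' initial scores. An edge between two seeds (initial score 1) of unit
#' weight has length 1; an edge between two non-seeds (0.01) has length
#' 100, so paths running through seed territory are short. The literal
#' product form `weight * (s_i + s_j) / 2` is available via
#' `form = "product"` (it inverts the intended ordering and is kept only
#' for comparison).
#'
#' @param weight edge weight (> 0)
#' @param s_i,s_j initial scores of the endpoints (>= 0, not both 0)
#' @param form `"inverse"` (default) or `"product"`
#' @return edge length(s)
#' @export
netshort_edge_length <- function(weight, s_i, s_j,
                                 form = c("inverse", "product")) {
  form <- match.arg(form)
  if (any(weight <= 0)) stop("edge weights must be positive")
  if (any(s_i < 0) || any(s_j < 0)) stop("initial scores must be non-negative")
  if (any(s_i + s_j == 0)) stop("degenerate initial scores: s_i + s_j = 0")
  if (form == "inverse") weight * 2 / (s_i + s_j) else weight * (s_i + s_j) / 2
}

#' NetShort: seed-proximity scoring over score-weighted shortest paths
#'
#' A node relevant to the phenotype should lie at short distance from the
#' seeds, where "distance" discounts path segments that run through seeds:
#' each edge gets length [netshort_edge_length()] and the score of node
#' `u` is the sum over seeds `v != u` of `seed_score(v) / d(u, v)` under
#' those lengths.
#'
#' @param net connected network
#' @param init initial score vector from [assign_initial_scores()]
#' @param seeds seed identifiers (nodes carrying the high initial score)
#' @param form edge-length form, see [netshort_edge_length()]
#' @return named numeric score vector
#' @export
netshort <- function(net, init, seeds, form = c("inverse", "product")) {
  form <- match.arg(form)
  init <- check_scores(init, net)
  if (!igraph::is_connected(net)) {
    stop("network is disconnected; extract the largest connected component first")
  }
  if (!all(seeds %in% names(init))) stop("seeds not in network")
  el <- igraph::as_data_frame(net, what = "edges")
  lens <- netshort_edge_length(el$weight, init[el$from], init[el$to],
                               form = form)
  d <- igraph::distances(net, v = seeds, weights = lens)  # |S| x n
  nodes <- network_nodes(net)
  contrib <- init[seeds] / d  # seed_score(v) / d(v, u); Inf on diagonal
  # a seed does not count its own (zero) distance
  contrib[d == 0] <- 0
  stats::setNames(colSums(contrib)[nodes], nodes)
}

#' Degree-preserving score permutations
#'
#' Builds the null ensemble used by NetZcore: `n` random node relabelings
#' in which every node is swapped only with nodes of identical degree.
#' Equivalently, the topology is fixed and the score assignment is permuted
#' within degree classes, which is how the ensemble is applied. Nodes whose
#' degree is unique in the network (typically hubs) are fixed points of
#' every permutation.
#'
#' @param net network
#' @param n ensemble size (default 100)
#' @param rng_seed integer seed for reproducibility (optional; when given,
#'   the RNG is seeded before drawing)
#' @return object of class `guild_ensemble`: a list with `permutations`
#'   (list of named character vectors mapping node -> node of equal
#'   degree), `nodes`, and `degrees`
#' @export
degree_preserving_permutations <- function(net, n = 100, rng_seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  nodes <- network_nodes(net)
  deg <- igraph::degree(net)
  classes <- split(seq_along(nodes), deg)
  perms <- vector("list", n)
  for (i in seq_len(n)) {
    p <- seq_along(nodes)
    for (cl in classes) {
      if (length(cl) > 1L) p[cl] <- cl[sample.int(length(cl))]
    }
    perms[[i]] <- stats::setNames(nodes[p], nodes)
  }
  structure(list(permutations = perms, nodes = nodes,
                 degrees = stats::setNames(as.integer(deg), nodes)),
            class = "guild_ensemble")
}

#' @export
print.guild_ensemble <- function(x, ...) {
  cat(sprintf("guild_ensemble: %d degree-preserving permutations over %d nodes\n",
              length(x$permutations), length(x$nodes)))
  invisible(x)
}

#' NetZcore: iterative z-score normalization against degree-matched nulls
#'
#' At each iteration the raw score of a node is the weight-normalized
#' average of its neighbors' current scores,
#' `raw(u) = sum_v w(u,v) s(v) / sum_v w(u,v)`. The same raw score is
#' recomputed under every permutation in a degree-preserving null ensemble,
#' giving a per-node null mean and standard deviation, and the node's new
#' score is the z-score of its observed raw value. Normalizing and
#' propagating at every iteration corrects the bias that highly connected
#' nodes attract score regardless of the phenotype.
#'
#' @param net network
#' @param init initial score vector
#' @param ensemble a `guild_ensemble` built on the same network (see
#'   [degree_preserving_permutations()])
#' @param max_z number of iterations (default 5)
#' @return named numeric score vector (z-scores; may be negative)
#' @export
netzcore <- function(net, init, ensemble, max_z = 5) {
  s <- check_scores(init, net)
  if (!inherits(ensemble, "guild_ensemble") ||
      !identical(sort(ensemble$nodes), sort(names(s)))) {
    stop("ensemble was not built on this network")
  }
  if (length(ensemble$permutations) == 0L) stop("empty ensemble")
  stopifnot(max_z >= 1)
  nodes <- network_nodes(net)
  W <- adjacency_weighted(net)
  wsum <- rowSums(W)
  wsum[wsum == 0] <- 1  # isolated node: raw score 0 either way
  # permutation index matrix: column j gives, for each node, the node whose
  # score it receives under permutation j
  P <- vapply(ensemble$permutations,
              function(p) match(p[nodes], nodes), integer(length(nodes)))
  for (k in seq_len(max_z)) {
    raw <- as.numeric(W %*% s[nodes]) / wsum
    S_perm <- matrix(s[nodes][P], nrow = length(nodes))
    raw_null <- (W %*% S_perm) / wsum
    mu <- rowMeans(raw_null)
    # the ensemble is the full reference population: population sd
    sigma <- sqrt(rowMeans(raw_null^2) - mu^2)
    sigma[sigma < .Machine$double.eps^0.5] <- 0
    z <- ifelse(sigma == 0, 0, (raw - mu) / sigma)
    s <- stats::setNames(z, nodes)
  }
  s
}

#' NetScore: shortest-path message passing
#'
#' Information spreads from every node along shortest paths only. Each node
#' starts a repetition holding one message from itself with path weight 1;
#' at every iteration all messages stored at a node are forwarded to its
#' neighbors with the path weight multiplied by the edge weight. A receiver
#' accepts messages from a given emitter only in the first iteration any
#' message from that emitter arrives — i.e. exactly the messages travelling
#' the shortest paths, counted with multiplicity when several shortest
#' paths tie. After `max_s` iterations a node's score is the mean over its
#' stored messages of (emitter's score at the start of the repetition) x
#' (path weight). Scores are then fixed, message stores emptied, and the
#' next of `nr` repetitions begins, which extends the effective horizon to
#' `max_s * nr` hops at bounded memory.
#'
#' @param net network
#' @param init initial score vector
#' @param max_s iterations per repetition (default 2)
#' @param nr repetitions (default 3)
#' @param self_message should each node's own score enter its average
#'   (emitter = self, path weight 1)? Default TRUE, so seeds retain high
#'   scores after propagation.
#' @return named numeric score vector
#' @export
netscore <- function(net, init, max_s = 2, nr = 3, self_message = TRUE) {
  s <- check_scores(init, net)
  stopifnot(max_s >= 1, nr >= 1)
  nodes <- network_nodes(net)
  n <- length(nodes)
  W <- adjacency_weighted(net)
  A <- (W > 0) * 1

  for (rep_i in seq_len(nr)) {
    s0 <- s[nodes]
    # PW[u, e]: summed path weights of accepted shortest paths e -> u
    # NC[u, e]: number of such paths; arrived: (u, e) already served
    PW <- diag(1, n); NC <- diag(1, n)
    arrived <- diag(n) > 0
    frontPW <- PW; frontNC <- NC
    for (k in seq_len(max_s)) {
      candPW <- W %*% frontPW
      candNC <- A %*% frontNC
      new <- (candNC > 0) & !arrived
      if (!any(new)) break
      frontPW <- ifelse(new, candPW, 0)
      frontNC <- ifelse(new, candNC, 0)
      PW <- PW + frontPW
      NC <- NC + frontNC
      arrived <- arrived | new
    }
    if (!self_message) {
      diag(PW) <- 0; diag(NC) <- 0
    }
    num <- as.numeric(PW %*% s0)
    cnt <- rowSums(NC)
    s <- stats::setNames(ifelse(cnt > 0, num / cnt, s0), nodes)
  }
  s
}

#' Z-normalize a score vector
#'
#' Subtracts the mean over nodes and divides by the sample standard
#' deviation (n-1 denominator). A constant vector maps to all zeros.
#'
#' @param scores named numeric vector
#' @return named numeric vector with mean 0 and sample sd 1 (unless
#'   degenerate)
#' @export
znormalize <- function(scores) {
  stopifnot(is.numeric(scores), length(scores) >= 2)
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) {
    return(stats::setNames(rep(0, length(scores)), names(scores)))
  }
  (scores - mean(scores)) / s
}

#' NetCombo: consensus of prioritization methods
#'
#' Averages the z-normalized score vectors of several methods; the default
#' combination in the framework is NetScore + NetZcore + NetShort. All
#' vectors must cover the same node set.
#'
#' @param score_vectors list of >= 2 named numeric vectors over identical
#'   node sets
#' @return named numeric consensus score vector
#' @export
netcombo <- function(score_vectors) {
  stopifnot(is.list(score_vectors), length(score_vectors) >= 2)
  nodes <- names(score_vectors[[1]])
  if (is.null(nodes)) stop("score vectors must be named")
  for (v in score_vectors[-1]) {
    if (!setequal(names(v), nodes)) stop("score vectors cover different node sets")
  }
  z <- vapply(score_vectors, function(v) znormalize(v[nodes]),
              numeric(length(nodes)))
  stats::setNames(rowMeans(z), nodes)
}
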