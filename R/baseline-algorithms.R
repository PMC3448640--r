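# Global-topology baseline algorithms: random walk with restart, PageRank
# with priors, network propagation, and functional flow. Each follows its
# original published formulation; the walk/propagation defaults here
# (restart 0.75, damping 0.85, alpha 0.8) are this package's configurable
# choices.

#' Parameters for the walk-based baselines
#'
#' @param restart_prob restart probability of the random walk in (0, 1\]
#'   (default 0.75)
#' @param damping PageRank damping factor in (0, 1) (default 0.85)
#' @param alpha propagation mixing weight in \[0, 1) (default 0.8)
#' @param tol convergence threshold on the L1 change per iteration
#'   (default 1e-6)
#' @param max_iter iteration cap (default 100)
#' @param max_f functional-flow iterations (default 5)
#' @return a `walk_params` list
#' @export
walk_params <- function(restart_prob = 0.75, damping = 0.85, alpha = 0.8,
                        tol = 1e-6, max_iter = 100, max_f = 5) {
  stopifnot(restart_prob > 0, restart_prob <= 1,
            damping > 0, damping < 1,
            alpha >= 0, alpha < 1,
            tol > 0, max_iter >= 1, max_f >= 1)
  structure(list(restart_prob = restart_prob, damping = damping,
                 alpha = alpha, tol = tol, max_iter = max_iter,
                 max_f = max_f), class = "walk_params")
}

# internal: column-stochastic normalization of the weighted adjacency
col_normalized_adjacency <- function(net) {
  W <- adjacency_weighted(net)
  cs <- colSums(W)
  cs[cs == 0] <- 1
  sweep(W, 2, cs, "/")
}

# internal: power iteration for p <- mix * M p + (1 - mix) * p0
power_iterate <- function(M, p0, mix, tol, max_iter, what) {
  p <- p0
  for (i in seq_len(max_iter)) {
    p_new <- mix * as.numeric(M %*% p) + (1 - mix) * p0
    if (sum(abs(p_new - p)) < tol) return(p_new)
    p <- p_new
  }
  resid <- sum(abs(mix * as.numeric(M %*% p) + (1 - mix) * p0 - p))
  stop(sprintf("%s did not converge in %d iterations (L1 residual %.3g)",
               what, max_iter, resid))
}

#' Random walk with restart
#'
#' Stationary distribution of a walker that at each step either follows an
#' edge of the column-normalized weighted adjacency (probability
#' `1 - restart_prob`) or teleports back to the normalized prior
#' distribution `p0` (probability `restart_prob`).
#'
#' @param net connected network
#' @param p0 non-negative prior score vector, not all zero (normalized
#'   internally to sum 1)
#' @param params a [walk_params()] object
#' @return named numeric vector summing to 1
#' @export
random_walk_with_restart <- function(net, p0, params = walk_params()) {
  p0 <- check_scores(p0, net)
  if (any(p0 < 0) || sum(p0) == 0) stop("p0 must be non-negative, not all zero")
  p0 <- p0 / sum(p0)
  r <- params$restart_prob
  if (r == 1) return(p0)
  M <- col_normalized_adjacency(net)
  p <- power_iterate(M, p0, mix = 1 - r, tol = params$tol,
                     max_iter = params$max_iter, what = "random walk with restart")
  stats::setNames(p, names(p0))
}

#' PageRank with priors
#'
#' Fixed point of `p <- (1 - damping) * priors + damping * W_col p`, the
#' personalized PageRank of the weighted network with the (normalized)
#' prior distribution as teleport target.
#'
#' @param net connected network
#' @param priors non-negative prior score vector, not all zero
#' @param params a [walk_params()] object
#' @return named numeric vector summing to 1
#' @export
pagerank_with_priors <- function(net, priors, params = walk_params()) {
  priors <- check_scores(priors, net)
  if (any(priors < 0) || sum(priors) == 0) {
    stop("priors must be non-negative, not all zero")
  }
  priors <- priors / sum(priors)
  M <- col_normalized_adjacency(net)
  p <- power_iterate(M, priors, mix = params$damping, tol = params$tol,
                     max_iter = params$max_iter, what = "PageRank with priors")
  stats::setNames(p, names(priors))
}

#' Network propagation
#'
#' Fixed point of `F <- alpha * W_sym F + (1 - alpha) * y`, where
#' `W_sym = D^{-1/2} A D^{-1/2}` is the symmetrically degree-normalized
#' weighted adjacency; equivalently the solution of
#' `(I - alpha W_sym) F = (1 - alpha) y`.
#'
#' @param net network
#' @param y non-negative prior score vector
#' @param params a [walk_params()] object
#' @return named numeric vector
#' @export
network_propagation <- function(net, y, params = walk_params()) {
  y <- check_scores(y, net)
  if (any(y < 0)) stop("prior vector must be non-negative")
  alpha <- params$alpha
  if (alpha == 0) return(y)
  W <- adjacency_weighted(net)
  d <- rowSums(W)
  d[d == 0] <- 1
  Wsym <- W / sqrt(outer(d, d))
  f <- y
  for (i in seq_len(params$max_iter)) {
    f_new <- alpha * as.numeric(Wsym %*% f) + (1 - alpha) * y
    if (sum(abs(f_new - f)) < params$tol) {
      return(stats::setNames(f_new, names(y)))
    }
    f <- f_new
  }
  stop(sprintf("network propagation did not converge in %d iterations",
               params$max_iter))
}

#' Functional flow
#'
#' Seeds hold infinite score reservoirs; over `max_f` discrete iterations
#' score flows along each edge from the fuller to the emptier endpoint,
#' capped by the edge weight and by the donor's reservoir spread
#' proportionally over its incident edge weights:
#' `flow(u -> v) = min(w(u,v), R(u) * w(u,v) / sum_y w(u,y))` when
#' `R(u) > R(v)`, else 0. Updates are synchronous. A node's final score is
#' its total accumulated inflow.
#'
#' @param net network
#' @param seeds seed node identifiers (infinite reservoirs)
#' @param max_f number of iterations (default 5)
#' @return named numeric vector of accumulated inflow (non-negative;
#'   seeds score 0 unless fed by a fuller neighbor, which cannot happen)
#' @export
functional_flow <- function(net, seeds, max_f = 5) {
  nodes <- network_nodes(net)
  if (length(seeds) == 0L || !all(seeds %in% nodes)) {
    stop("seeds must be a non-empty subset of the network's nodes")
  }
  stopifnot(max_f >= 1)
  W <- adjacency_weighted(net)
  wout <- rowSums(W)
  wout[wout == 0] <- 1
  R <- stats::setNames(rep(0, length(nodes)), nodes)
  R[seeds] <- Inf
  inflow_total <- stats::setNames(rep(0, length(nodes)), nodes)
  for (t in seq_len(max_f)) {
    # proportional share of the donor's reservoir, capped at edge weight
    share <- W * (R / wout)           # share[u, v] = w(u,v) * R(u) / sum_y w(u,y)
    share[W == 0] <- 0                # kills Inf * 0 from seed rows
    flow <- pmin(W, share)
    downhill <- outer(R, R, ">")      # R(u) > R(v)
    flow[!downhill] <- 0
    inflow <- colSums(flow)
    outflow <- rowSums(flow)
    inflow_total <- inflow_total + inflow
    R_new <- R + inflow - outflow
    R_new[R == Inf] <- Inf            # seed reservoirs never deplete
    R <- R_new
  }
  inflow_total
}
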