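# Independent oracles and small random-instance generators used across the
# suite. Everything here is deliberately naive (Floyd-Warshall, recursive
# path enumeration, direct linear solves) and shares no code path with the
# package implementations it checks.

# random connected graph: random spanning tree plus `extra` random edges
random_connected_edges <- function(n, extra = n, weighted = FALSE) {
  stopifnot(n >= 2)
  ids <- sprintf("v%02d", seq_len(n))
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1), 1L))
  from <- ids[parent[-1]]
  to <- ids[-1]
  if (extra > 0) {
    for (i in seq_len(extra)) {
      pr <- sample.int(n, 2)
      from <- c(from, ids[pr[1]]); to <- c(to, ids[pr[2]])
    }
  }
  keep <- from != to
  data.frame(from = from[keep], to = to[keep],
             weight = if (weighted) round(runif(sum(keep), 1, 2), 3) else 1,
             stringsAsFactors = FALSE)
}

random_connected_net <- function(n, extra = n, weighted = FALSE) {
  suppressWarnings(network_from_edges(random_connected_edges(n, extra, weighted)))
}

# dense symmetric matrix of edge lengths (Inf where no edge) for a network,
# built from the edge data frame, not from the package's adjacency helper
edge_length_matrix <- function(net, lengths = NULL) {
  nodes <- sort(igraph::V(net)$name)
  el <- igraph::as_data_frame(net, what = "edges")
  if (is.null(lengths)) lengths <- el$weight
  m <- matrix(Inf, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  diag(m) <- 0
  for (i in seq_len(nrow(el))) {
    a <- el$from[i]; b <- el$to[i]
    m[a, b] <- m[b, a] <- min(m[a, b], lengths[i])
  }
  m
}

# Floyd-Warshall all-pairs shortest paths
oracle_floyd <- function(len) {
  n <- nrow(len)
  d <- len
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

# brute-force NetShort: Floyd-Warshall on the score-dependent edge lengths,
# then the inverse-distance-weighted sum of seed scores
oracle_netshort <- function(net, init, seeds) {
  el <- igraph::as_data_frame(net, what = "edges")
  lens <- el$weight * 2 / (init[el$from] + init[el$to])
  d <- oracle_floyd(edge_length_matrix(net, lens))
  nodes <- igraph::V(net)$name
  sapply(nodes, function(u) {
    sum(vapply(setdiff(seeds, u), function(v) init[[v]] / d[u, v], 1))
  })
}

# adjacency lookup for the path enumerator
neighbor_list <- function(net) {
  el <- igraph::as_data_frame(net, what = "edges")
  nodes <- igraph::V(net)$name
  nb <- setNames(vector("list", length(nodes)), nodes)
  w <- list()
  for (i in seq_len(nrow(el))) {
    a <- el$from[i]; b <- el$to[i]
    nb[[a]] <- c(nb[[a]], b); nb[[b]] <- c(nb[[b]], a)
    w[[paste(a, b)]] <- el$weight[i]; w[[paste(b, a)]] <- el$weight[i]
  }
  list(nb = nb, w = w)
}

# enumerate all hop-shortest paths from e to every node by exhaustive DFS
# expansion up to the hop distance; returns per target the number of
# shortest paths and the sum of their edge-weight products
oracle_shortest_paths <- function(net, emitter) {
  adj <- neighbor_list(net)
  nodes <- igraph::V(net)$name
  hops <- oracle_floyd(edge_length_matrix(net, rep(1, igraph::ecount(net))))
  npaths <- setNames(rep(0, length(nodes)), nodes)
  sumpw <- setNames(rep(0, length(nodes)), nodes)
  walk <- function(u, depth, pw) {
    if (depth == hops[emitter, u]) {
      npaths[u] <<- npaths[u] + 1
      sumpw[u] <<- sumpw[u] + pw
    }
    if (depth >= max(hops[emitter, is.finite(hops[emitter, ])])) return()
    for (v in adj$nb[[u]]) {
      if (depth + 1 <= hops[emitter, v]) {
        walk(v, depth + 1, pw * adj$w[[paste(u, v)]])
      }
    }
  }
  walk(emitter, 0, 1)
  list(npaths = npaths, sumpw = sumpw)
}

# NetScore oracle for one repetition with horizon >= diameter: every node's
# score is the mean over self plus all shortest-path messages
oracle_netscore_one_rep <- function(net, init) {
  nodes <- igraph::V(net)$name
  per_emitter <- lapply(setNames(nodes, nodes),
                        function(e) oracle_shortest_paths(net, e))
  sapply(nodes, function(u) {
    num <- init[[u]]  # self-message
    cnt <- 1
    for (e in setdiff(nodes, u)) {
      sp <- per_emitter[[e]]
      num <- num + init[[e]] * sp$sumpw[[u]]
      cnt <- cnt + sp$npaths[[u]]
    }
    num / cnt
  })
}

# column-normalized and symmetric-normalized adjacency built from the edge
# table (independent of the package's internal helpers)
oracle_adjacency <- function(net) {
  nodes <- sort(igraph::V(net)$name)
  el <- igraph::as_data_frame(net, what = "edges")
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(el))) {
    A[el$from[i], el$to[i]] <- A[el$to[i], el$from[i]] <- el$weight[i]
  }
  A
}

oracle_rwr_solve <- function(net, p0, r) {
  A <- oracle_adjacency(net)
  Wcol <- sweep(A, 2, colSums(A), "/")
  p0 <- p0[rownames(A)] / sum(p0)
  solve(diag(nrow(A)) - (1 - r) * Wcol, r * p0)
}

oracle_pagerank_solve <- function(net, priors, beta) {
  A <- oracle_adjacency(net)
  Wcol <- sweep(A, 2, colSums(A), "/")
  priors <- priors[rownames(A)] / sum(priors)
  solve(diag(nrow(A)) - beta * Wcol, (1 - beta) * priors)
}

oracle_propagation_solve <- function(net, y, alpha) {
  A <- oracle_adjacency(net)
  d <- rowSums(A)
  Wsym <- A / sqrt(outer(d, d))
  y <- y[rownames(A)]
  solve(diag(nrow(A)) - alpha * Wsym, (1 - alpha) * y)
}

# all permutations of 1..n (for exhaustive null ensembles on tiny graphs)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

# exhaustive degree-preserving ensemble (tiny graphs only)
exhaustive_ensemble <- function(net) {
  nodes <- igraph::V(net)$name
  deg <- igraph::degree(net)
  classes <- split(seq_along(nodes), deg)
  class_perms <- lapply(classes, function(cl) {
    lapply(all_permutations(length(cl)), function(p) cl[p])
  })
  grids <- expand.grid(lapply(class_perms, seq_along))
  perms <- lapply(seq_len(nrow(grids)), function(i) {
    p <- seq_along(nodes)
    for (j in seq_along(classes)) {
      p[classes[[j]]] <- class_perms[[j]][[grids[i, j]]]
    }
    setNames(nodes[p], nodes)
  })
  structure(list(permutations = perms, nodes = nodes,
                 degrees = setNames(as.integer(deg), nodes)),
            class = "guild_ensemble")
}

# tiny named path / cycle builders
path_net <- function(ids, weights = NULL) {
  n <- length(ids)
  df <- data.frame(from = ids[-n], to = ids[-1])
  if (!is.null(weights)) df$weight <- weights
  network_from_edges(df)
}

cycle_net <- function(ids) {
  network_from_edges(data.frame(from = ids, to = c(ids[-1], ids[1])))
}
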