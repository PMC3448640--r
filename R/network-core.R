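# Graph data model and file I/O.
#
# Networks are undirected igraph objects with a character `name` vertex
# attribute and a numeric `weight` edge attribute (dimensionless interaction
# confidence, default 1). Score vectors are numeric vectors named by node.

#' Build a network from an edge table
#'
#' Constructs an undirected, weighted network from a data frame of edges.
#' Duplicate edges (in either orientation) are collapsed to a single edge
#' keeping the maximum weight; self-loops are dropped with a warning.
#'
#' @param edges data frame with columns `from`, `to` and optionally `weight`
#'   (default 1). Node identifiers are coerced to character.
#' @return An undirected igraph object with vertex names and edge weights.
#' @export
#' @examples
#' net <- network_from_edges(data.frame(from = c("A", "B"), to = c("B", "C")))
#' igraph::vcount(net)
network_from_edges <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  weight <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else
    rep(1, length(from))
  if (anyNA(weight)) stop("non-numeric edge weight")
  if (any(weight < 0)) stop("edge weights must be non-negative")

  loops <- from == to
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    from <- from[!loops]; to <- to[!loops]; weight <- weight[!loops]
  }
  if (length(from) == 0L) stop("no edges after removing self-loops")

  # canonical orientation so (u,v) and (v,u) collapse together
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  w <- tapply(weight, key, max)
  keep <- !duplicated(key)
  g <- igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE),
    directed = FALSE
  )
  igraph::E(g)$weight <- as.numeric(w[paste(a[keep], b[keep], sep = "\r")])
  g
}

#' Node identifiers of a network
#' @param net network (igraph object)
#' @return character vector of node names
#' @export
network_nodes <- function(net) {
  as.character(igraph::V(net)$name)
}

#' Read a network from an edge-list file
#'
#' Two whitespace-delimited dialects are supported. The `guild` dialect puts
#' the weight in the middle column (`node1 weight node2`); the `plain`
#' dialect is `node1 node2 [weight]` with a default weight of 1. The dialect
#' is never auto-detected because a three-column plain file is ambiguous with
#' the guild layout. Lines starting with `#` and blank lines are ignored.
#' Duplicate edges keep the maximum weight; self-loops are dropped with a
#' warning.
#'
#' @param path path to the edge-list file
#' @param dialect `"guild"` or `"plain"`
#' @return an undirected weighted network
#' @export
read_network <- function(path, dialect = c("guild", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("empty network file: ", path)

  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  parse_fail <- function(i, why) {
    stop(sprintf("parse error at line %d of %s: %s", lineno[i], path, why))
  }
  if (dialect == "guild") {
    bad <- which(nf != 3L)
    if (length(bad)) parse_fail(bad[1], "expected 3 fields (node1 weight node2)")
    from <- vapply(fields, `[[`, "", 1L)
    to <- vapply(fields, `[[`, "", 3L)
    wtxt <- vapply(fields, `[[`, "", 2L)
  } else {
    bad <- which(nf < 2L | nf > 3L)
    if (length(bad)) parse_fail(bad[1], "expected 2 or 3 fields (node1 node2 [weight])")
    from <- vapply(fields, `[[`, "", 1L)
    to <- vapply(fields, `[[`, "", 2L)
    wtxt <- vapply(fields, function(f) if (length(f) == 3L) f[[3L]] else "1", "")
  }
  weight <- suppressWarnings(as.numeric(wtxt))
  if (anyNA(weight)) {
    parse_fail(which(is.na(weight))[1], sprintf("non-numeric weight '%s'",
                                                wtxt[which(is.na(weight))[1]]))
  }
  network_from_edges(data.frame(from = from, to = to, weight = weight,
                                stringsAsFactors = FALSE))
}

#' Write a network to an edge-list file
#'
#' Inverse of [read_network()]; the same dialect conventions apply.
#'
#' @param net network
#' @param path output path
#' @param dialect `"guild"` or `"plain"`
#' @return `path`, invisibly
#' @export
write_network <- function(net, path, dialect = c("guild", "plain")) {
  dialect <- match.arg(dialect)
  el <- igraph::as_data_frame(net, what = "edges")
  if (is.null(el$weight)) el$weight <- 1
  out <- if (dialect == "guild") {
    sprintf("%s %s %s", el$from, format(el$weight, trim = TRUE, digits = 15),
            el$to)
  } else {
    sprintf("%s %s %s", el$from, el$to,
            format(el$weight, trim = TRUE, digits = 15))
  }
  writeLines(out, path)
  invisible(path)
}

#' Largest connected component
#'
#' Returns the induced subgraph on the largest connected component.
#' Information can only flow along edges, so all scoring algorithms operate
#' on a connected network; callers extract the LCC first. Ties between
#' equal-sized components are broken deterministically in favour of the
#' component containing the lexicographically smallest node identifier.
#'
#' @param net network
#' @return connected network
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # smallest lexicographic member identifies the winner
    firsts <- vapply(best, function(ci) {
      min(igraph::V(net)$name[comp$membership == ci])
    }, "")
    best <- best[order(firsts)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Apply STRING-style confidence scores as edge weights
#'
#' Raw confidence scores on the STRING scale (0 to 1000) are rescaled to
#' \[0,1\] by dividing by 1000 and added to the default weight 1, so
#' covered edges carry weights in \[1,2\] and uncovered edges keep weight 1.
#' Dividing by the fixed score ceiling (rather than min-max over the
#' observed edges) keeps weights stable under network subsetting; min-max
#' rescaling is available via `rescale = "minmax"`.
#'
#' @param net network
#' @param confidence data frame with columns `from`, `to`, `score`
#'   (raw scores in \[0,1000\]); orientation is ignored
#' @param rescale `"fixed"` (divide by 1000) or `"minmax"` (affine map of
#'   the observed score range onto \[0,1\])
#' @return network with updated edge weights, all in \[1,2\]
#' @export
apply_confidence_weights <- function(net, confidence,
                                     rescale = c("fixed", "minmax")) {
  rescale <- match.arg(rescale)
  stopifnot(is.data.frame(confidence),
            all(c("from", "to", "score") %in% names(confidence)))
  raw <- as.numeric(confidence$score)
  if (anyNA(raw) || any(raw < 0 | raw > 1000)) {
    stop("confidence scores must lie in [0, 1000]")
  }
  scaled <- if (rescale == "fixed") {
    raw / 1000
  } else {
    rng <- range(raw)
    if (diff(rng) == 0) rep(0, length(raw)) else (raw - rng[1]) / diff(rng)
  }
  a <- pmin(as.character(confidence$from), as.character(confidence$to))
  b <- pmax(as.character(confidence$from), as.character(confidence$to))
  lut <- stats::setNames(scaled, paste(a, b, sep = "\r"))

  el <- igraph::as_data_frame(net, what = "edges")
  ekey <- paste(pmin(el$from, el$to), pmax(el$from, el$to), sep = "\r")
  add <- lut[ekey]
  add[is.na(add)] <- 0
  igraph::E(net)$weight <- 1 + as.numeric(add)
  net
}

#' Read a seed list
#'
#' One node identifier per line; `#` comments and blank lines ignored. An
#' optional second column (a per-seed score) is tolerated and discarded.
#' Duplicate identifiers are collapsed with a warning.
#'
#' @param path path to the seed file
#' @return character vector of seed identifiers
#' @export
read_seeds <- function(path) {
  if (!file.exists(path)) stop("seed file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty seed file: ", path)
  ids <- vapply(strsplit(trimws(lines), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    warning(sprintf("%d duplicate seed line(s) collapsed",
                    sum(duplicated(ids))))
    ids <- unique(ids)
  }
  ids
}

#' Restrict a seed set to the nodes of a network
#'
#' Seeds absent from the network are dropped explicitly, with a warning
#' listing them; restriction is never silent.
#'
#' @param seeds character vector of seed identifiers
#' @param net network
#' @return seeds present in `net`
#' @export
restrict_seeds <- function(seeds, net) {
  nodes <- network_nodes(net)
  missing <- setdiff(seeds, nodes)
  if (length(missing)) {
    warning(sprintf("dropped %d seed(s) not in the network: %s",
                    length(missing), paste(missing, collapse = ", ")))
  }
  kept <- intersect(seeds, nodes)
  if (length(kept) == 0L) stop("no seeds remain after restriction to network")
  kept
}

#' Write node scores to a two-column table
#'
#' Tab-separated `node<TAB>score`, sorted by descending score (ties by node
#' identifier).
#'
#' @param scores named numeric vector of node scores
#' @param path output path
#' @return `path`, invisibly
#' @export
write_scores <- function(scores, path) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  ord <- order(-scores, names(scores))
  writeLines(sprintf("%s\t%s", names(scores)[ord],
                     format(scores[ord], trim = TRUE, digits = 15)), path)
  invisible(path)
}

#' Read node scores written by [write_scores()]
#' @param path path to a two-column `node<TAB>score` table
#' @return named numeric vector
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("node", "score"),
                           colClasses = c("character", "numeric"))
  stats::setNames(tab$score, tab$node)
}

# internal: weighted adjacency matrix in a fixed node order
adjacency_weighted <- function(net) {
  m <- igraph::as_adjacency_matrix(net, attr = "weight", sparse = FALSE)
  storage.mode(m) <- "double"
  m
}

# internal: assert scores cover exactly the network's nodes
check_scores <- function(scores, net) {
  nodes <- network_nodes(net)
  if (is.null(names(scores)) || !setequal(names(scores), nodes)) {
    stop("score vector must be named by exactly the network's nodes")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  scores[nodes]
}
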