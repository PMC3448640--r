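test_that("initial scores form the exact two-level vector", {
  net <- path_net(c("A", "B", "C"))
  expect_equal(assign_initial_scores(net, "A"),
               c(A = 1.00, B = 0.01, C = 0.01))
  expect_equal(unname(assign_initial_scores(net, c("A", "B", "C"))),
               rep(1, 3))
  expect_equal(unname(assign_initial_scores(net, "A", nonseed_score = 0)[c("B", "C")]),
               c(0, 0))
  expect_error(assign_initial_scores(net, character()), "empty")
  expect_error(assign_initial_scores(net, "A", seed_score = 0.01,
                                     nonseed_score = 0.01))
})

test_that("NetShort edge length realizes 'seed edges are short'", {
  expect_equal(netshort_edge_length(1, 1, 1), 1)
  expect_equal(netshort_edge_length(1, 0.01, 0.01), 100)
  # linear in weight, decreasing in endpoint scores
  expect_equal(netshort_edge_length(2, 0.4, 0.6), 2 * netshort_edge_length(1, 0.4, 0.6))
  expect_lt(netshort_edge_length(1, 1, 0.5), netshort_edge_length(1, 0.2, 0.5))
  expect_error(netshort_edge_length(1, 0, 0), "degenerate")
  # literal product form kept for comparison, inverted ordering
  expect_equal(netshort_edge_length(1, 1, 1, form = "product"), 1)
  expect_lt(netshort_edge_length(1, 0.01, 0.01, form = "product"), 1)
})

test_that("NetShort on a seeded path matches the Dijkstra hand computation", {
  net <- path_net(c("A", "B", "C"))
  init <- assign_initial_scores(net, "A")
  sc <- netshort(net, init, "A")
  expect_equal(sc[["B"]], 1 / (2 / 1.01), tolerance = 1e-12)
  expect_equal(sc[["C"]], 1 / (2 / 1.01 + 100), tolerance = 1e-12)
  expect_gt(sc[["B"]], sc[["C"]])
})

test_that("NetShort agrees with the all-pairs Floyd-Warshall oracle", {
  set.seed(11)
  for (i in 1:10) {
    net <- random_connected_net(sample(5:25, 1), extra = sample(5:20, 1),
                                weighted = TRUE)
    seeds <- sample(network_nodes(net), sample(2:4, 1))
    init <- assign_initial_scores(net, seeds)
    expect_equal(netshort(net, init, seeds),
                 oracle_netshort(net, init, seeds)[network_nodes(net)],
                 tolerance = 1e-9)
  }
})

test_that("NetShort refuses disconnected networks", {
  net <- network_from_edges(data.frame(from = c("A", "C"), to = c("B", "D")))
  init <- assign_initial_scores(net, "A")
  expect_error(netshort(net, init, "A"), "connected component")
})

test_that("degree-preserving permutations fix degree and conserve scores", {
  # star: hub is a singleton degree class, hence a fixed point
  star <- network_from_edges(data.frame(from = "hub", to = c("a", "b", "c")))
  ens <- degree_preserving_permutations(star, n = 25, rng_seed = 3)
  expect_length(ens$permutations, 25)
  for (p in ens$permutations) {
    expect_identical(p[["hub"]], "hub")
    expect_setequal(unname(p[c("a", "b", "c")]), c("a", "b", "c"))
  }

  set.seed(5)
  for (i in 1:5) {
    net <- random_connected_net(30, extra = 25)
    deg <- igraph::degree(net)
    ens <- degree_preserving_permutations(net, n = 20)
    sc <- setNames(runif(igraph::vcount(net)), network_nodes(net))
    for (p in ens$permutations) {
      expect_true(all(deg[p] == deg[names(p)]))           # degree preserved
      expect_setequal(unname(sc[p]), unname(sc))          # score multiset conserved
    }
  }

  # reproducible from the seed
  e1 <- degree_preserving_permutations(star, n = 5, rng_seed = 99)
  e2 <- degree_preserving_permutations(star, n = 5, rng_seed = 99)
  expect_identical(e1$permutations, e2$permutations)
})

test_that("NetZcore matches the exhaustive-ensemble null moments", {
  cyc <- cycle_net(c("A", "B", "C", "D"))
  init <- assign_initial_scores(cyc, "A")
  ens <- exhaustive_ensemble(cyc)
  expect_length(ens$permutations, 24)
  z <- netzcore(cyc, init, ens, max_z = 1)
  # raw(u) = mean of neighbor scores; null mean over all 24 permutations is
  # mean over ordered score pairs without replacement: mu = 0.2575,
  # population sigma = 0.2475, giving z = -1 off-seed-adjacent, +1 adjacent
  expect_equal(z, c(A = -1, B = 1, C = -1, D = 1), tolerance = 1e-12)
})

test_that("NetZcore symmetry and zero-variance guard", {
  cyc <- cycle_net(sprintf("c%d", 1:6))
  init <- assign_initial_scores(cyc, c("c1", "c4"))  # antipodal seeds
  ens <- exhaustive_ensemble(cyc)  # 720 permutations: exact null moments
  z <- netzcore(cyc, init, ens, max_z = 3)
  # automorphism c2<->c6, c3<->c5 fixes the seed set
  expect_equal(z[["c2"]], z[["c6"]], tolerance = 1e-12)
  expect_equal(z[["c3"]], z[["c5"]], tolerance = 1e-12)

  # all nodes same degree and same score: every permutation gives the same
  # raw score, sigma = 0, guarded to z = 0
  const <- setNames(rep(1, 6), network_nodes(cyc))
  z0 <- netzcore(cyc, const, ens, max_z = 2)
  expect_equal(unname(z0), rep(0, 6))
})

test_that("NetScore propagates along shortest paths with multiplicity", {
  ab <- path_net(c("A", "B"))
  sc <- netscore(ab, assign_initial_scores(ab, "A"), max_s = 1, nr = 1)
  expect_equal(sc, c(A = 0.505, B = 0.505))

  # square: two tied 2-hop shortest paths double-count the opposite node
  sq <- cycle_net(c("A", "B", "C", "D"))
  init <- assign_initial_scores(sq, "A")
  sc <- netscore(sq, init, max_s = 2, nr = 1)
  # C stores: self (0.01), B and D at 1 hop (0.01 each), A twice at 2 hops
  expect_equal(sc[["C"]], (0.01 * 3 + 1.00 * 2) / 5)

  # without the self-message the seed's own score leaves its average
  sc_ns <- netscore(ab, assign_initial_scores(ab, "A"), max_s = 1, nr = 1,
                    self_message = FALSE)
  expect_equal(sc_ns, c(A = 0.01, B = 1.00))
})

test_that("NetScore agrees with the exhaustive path-enumeration oracle", {
  set.seed(21)
  for (i in 1:10) {
    net <- random_connected_net(sample(4:8, 1), extra = sample(2:6, 1),
                                weighted = TRUE)
    seeds <- sample(network_nodes(net), 2)
    init <- assign_initial_scores(net, seeds)
    diam <- igraph::diameter(net, weights = NA)
    expect_equal(netscore(net, init, max_s = diam, nr = 1),
                 oracle_netscore_one_rep(net, init)[network_nodes(net)],
                 tolerance = 1e-12)
  }
})

test_that("NetScore is invariant under seed-fixing automorphisms", {
  cyc <- cycle_net(sprintf("c%d", 1:6))
  init <- assign_initial_scores(cyc, "c1")
  sc <- netscore(cyc, init, max_s = 2, nr = 3)
  expect_equal(sc[["c2"]], sc[["c6"]], tolerance = 1e-12)
  expect_equal(sc[["c3"]], sc[["c5"]], tolerance = 1e-12)
})

test_that("z-normalization and NetCombo consensus behave as defined", {
  v <- setNames(c(1, 2, 3), c("A", "B", "C"))
  expect_equal(znormalize(v), setNames(c(-1, 0, 1), c("A", "B", "C")))
  expect_equal(unname(znormalize(setNames(rep(4, 5), letters[1:5]))), rep(0, 5))
  set.seed(2)
  r <- setNames(rnorm(50), sprintf("n%d", 1:50))
  expect_equal(mean(znormalize(r)), 0, tolerance = 1e-12)
  expect_equal(sd(znormalize(r)), 1, tolerance = 1e-12)

  expect_equal(netcombo(list(v, v, v)), znormalize(v))
  w <- setNames(c(3, 2, 1), c("A", "B", "C"))
  expect_equal(unname(netcombo(list(v, w))), rep(0, 3))
  # order of the input list is irrelevant; node order within vectors too
  expect_equal(netcombo(list(v, w)),
               netcombo(list(w[c("C", "A", "B")], v))[c("A", "B", "C")])
  expect_error(netcombo(list(v, setNames(1:3, c("A", "B", "X")))),
               "different node sets")
})

test_that("seeds outrank non-seeds on a planted module for all four methods", {
  cfg <- fixture_config(n_nodes = 120, n_seeds = 10, seed_mode = "clustered",
                        rng_seed = 31)
  net <- generate_network(cfg)
  seeds <- plant_seeds(net, cfg)
  for (m in c("netshort", "netscore", "netzcore", "netcombo")) {
    sc <- guild_score(net, seeds, method = m, rng_seed = 17)
    rk <- rank(-sc)
    expect_lt(mean(rk[seeds]), mean(rk[setdiff(names(sc), seeds)]))
  }
})
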