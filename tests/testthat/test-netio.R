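test_that("edge-list reading collapses duplicates, loops and weights", {
  f <- tempfile()
  writeLines(c("0 1", "1 0", "1 1", "1 2 0.7"), f)
  g <- read_edge_list(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_true(igraph::is_simple(g))

  # arbitrary string labels relabel consistently
  writeLines(c("a b", "b c", "# comment"), f)
  g <- read_edge_list(f)
  expect_equal(igraph::vcount(g), 3)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))

  # malformed lines are reported with their line number
  writeLines(c("0 1", "lonely"), f)
  expect_error(read_edge_list(f), "line 2")
  writeLines(character(0), f)
  expect_error(read_edge_list(f), "empty")
  expect_error(read_edge_list(tempfile()), "not found")
})

test_that("write + read round-trips the canonical simple graph", {
  for (g in list(graph_fixture("cycle", n = 6),
                 graph_fixture("two_cliques_bridged", n = 4),
                 giant_component(generate_configuration_network(200, 2.5, seed = 2)))) {
    f <- write_temp_edges(g)
    g2 <- read_edge_list(f)
    expect_equal(igraph::vcount(g2), igraph::vcount(g))
    # compare as unlabeled edge sets under the 0-based relabeling
    expect_equal(igraph::ecount(g2), igraph::ecount(g))
    expect_equal(sort(unname(igraph::degree(g2))),
                 sort(unname(igraph::degree(g))))
  }
})

test_that("giant component extraction is connected and tie-stable", {
  two_tri <- igraph::disjoint_union(igraph::make_full_graph(3),
                                    igraph::make_full_graph(3))
  gc <- giant_component(two_tri)
  expect_equal(igraph::vcount(gc), 3)
  expect_true(igraph::is_connected(gc))

  # a connected graph maps to itself
  g <- graph_fixture("cycle", n = 7)
  expect_equal(igraph::vcount(giant_component(g)), 7)

  # edgeless graph: a single node survives
  expect_equal(igraph::vcount(giant_component(igraph::make_empty_graph(5, directed = FALSE))), 1)
})

test_that("degree moments match direct arithmetic", {
  reg <- graph_fixture("regular", n = 10, k = 4, seed = 1)
  expect_equal(degree_stats(reg), list(mean_k = 4, mean_k2 = 16, k_min = 4, k_max = 4))

  st <- graph_fixture("star", n = 4)                 # degrees 4,1,1,1,1
  ds <- degree_stats(st)
  expect_equal(ds$mean_k, 8 / 5)
  expect_equal(ds$mean_k2, 4)

  k2 <- igraph::make_full_graph(2)
  expect_equal(degree_stats(k2)$mean_k, 1)
  expect_equal(degree_stats(k2)$mean_k2, 1)

  # Jensen: <k^2> >= <k>^2 on every loaded network
  for (g in random_config_suite(5, 100)) {
    ds <- degree_stats(g)
    expect_gte(ds$mean_k2, ds$mean_k^2)
  }
})

test_that("assortativity matches the oriented-edge Pearson formula", {
  expect_warning(r <- net_assortativity(graph_fixture("cycle", n = 8)),
                 "undefined")
  expect_true(is.na(r))

  expect_equal(net_assortativity(path_graph(4)), -0.5)

  # independent cross-check against igraph's estimator on random graphs
  for (g in random_config_suite(5, 120, master_seed = 7)) {
    expect_equal(suppressWarnings(net_assortativity(g)),
                 igraph::assortativity_degree(g), tolerance = 1e-12)
  }
})

test_that("clustering is the mean local coefficient with degree<2 as zero", {
  expect_equal(as.numeric(net_clustering(igraph::make_full_graph(3))), 1)
  expect_equal(as.numeric(net_clustering(path_graph(5))), 0)
  # K4 minus one edge: two nodes with c_i = 1, two with c_i = 2/3
  k4m <- igraph::delete_edges(igraph::make_full_graph(4), 1)
  expect_equal(as.numeric(net_clustering(k4m)), (1 + 1 + 2 / 3 + 2 / 3) / 4)
  # global transitivity rides along for diagnostics
  expect_true(!is.null(attr(net_clustering(k4m), "transitivity")))
})

test_that("modularity of the greedy partition is reproducible and sane", {
  tc <- graph_fixture("two_cliques_bridged", n = 5)
  md <- net_modularity(tc, seed = 1)
  # oracle lower bound: Q of the explicit two-clique partition
  q_two <- igraph::modularity(tc, rep(1:2, each = 5))
  expect_gt(md$Q, 0.3)
  expect_gte(md$Q + 1e-12, q_two)

  # complete graph: no community structure
  expect_lt(abs(net_modularity(igraph::make_full_graph(6))$Q), 0.2)

  # determinism
  expect_equal(net_modularity(tc, seed = 1)$Q, md$Q)
})

test_that("maximum k-core follows iterative pruning", {
  expect_equal(max_kcore(path_graph(6)), 1)
  expect_equal(max_kcore(igraph::make_full_graph(5)), 4)
  pend <- igraph::add_edges(igraph::add_vertices(igraph::make_full_graph(4), 1),
                            c(1, 5))
  expect_equal(max_kcore(pend), 3)
})

test_that("structure_metrics assembles one well-formed row", {
  g <- giant_component(generate_configuration_network(300, 2.5, seed = 9))
  sm <- structure_metrics(g, name = "toy")
  expect_equal(nrow(sm), 1)
  expect_named(sm, c("name", "N", "E", "mean_k", "mean_k2", "kmax", "r", "c",
                     "Q", "kcore_max"))
  expect_true(sm$c >= 0 && sm$c <= 1)
  expect_true(sm$Q >= -0.5 && sm$Q <= 1)
})
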