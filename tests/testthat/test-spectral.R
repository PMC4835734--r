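test_that("IPR has its closed-form values and bounds", {
  expect_equal(ipr(rep(1, 100)), 0.01)
  expect_equal(ipr(c(0, 1, 0, 0)), 1)
  expect_equal(ipr(c(1, 1, rep(0, 8))), 0.5)
  expect_error(ipr(rep(0, 4)), "zero")
  for (g in random_config_suite(3, 100, master_seed = 20)) {
    s <- adjacency_leading(g)
    expect_gte(s$ipr, 1 / igraph::vcount(g) - 1e-12)
    expect_lte(s$ipr, 1)
  }
})

test_that("adjacency leading eigenpair matches Perron theory on fixtures", {
  reg <- graph_fixture("regular", n = 10, k = 4, seed = 1)
  s <- adjacency_leading(reg)
  expect_equal(s$leading_eigenvalue, 4, tolerance = 1e-10)
  expect_equal(s$ipr, 1 / 10, tolerance = 1e-8)        # uniform Perron vector

  expect_equal(adjacency_leading(graph_fixture("star", n = 4))$leading_eigenvalue,
               2, tolerance = 1e-10)
  expect_equal(adjacency_leading(graph_fixture("clique", n = 4))$leading_eigenvalue,
               3, tolerance = 1e-10)

  s <- adjacency_leading(graph_fixture("star", n = 9))
  expect_equal(sum(s$principal_vector^2), 1, tolerance = 1e-12)
  expect_true(all(s$principal_vector >= 0))
})

test_that("the non-backtracking block matrix has the documented structure", {
  k2 <- igraph::make_full_graph(2)
  M <- as.matrix(nb_matrix(k2))
  expect_equal(unname(M),
               rbind(c(0, 1, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0)))
  ev <- eigen(M, only.values = TRUE)$values
  expect_equal(sort(Mod(ev[Mod(ev) > 1e-10])), c(1, 1))   # nonzero spectrum is +-1

  # linear operator: zero in, zero out
  M6 <- nb_matrix(graph_fixture("cycle", n = 6))
  expect_equal(as.numeric(M6 %*% rep(0, 12)), rep(0, 12))
})

test_that("non-backtracking leading eigenvalue has its closed forms", {
  expect_equal(nb_leading(graph_fixture("clique", n = 4))$leading_eigenvalue,
               2, tolerance = 1e-8)
  expect_equal(nb_leading(graph_fixture("cycle", n = 6))$leading_eigenvalue,
               1, tolerance = 1e-8)
  reg <- graph_fixture("regular", n = 30, k = 6, seed = 2)
  expect_equal(nb_leading(reg)$leading_eigenvalue, 5, tolerance = 1e-8)

  # trees have no non-backtracking orbit
  expect_error(nb_leading(path_graph(5)), "no cycle")
})

test_that("block-matrix and directed-edge-matrix eigenvalues agree", {
  for (g in fixture_suite()) {
    expect_equal(nb_leading(g)$leading_eigenvalue, nb_edge_oracle(g),
                 tolerance = 1e-8)
  }
})

test_that("non-backtracking centrality is degree-proportional on uncorrelated nets", {
  g <- giant_component(generate_configuration_network(10000, 3.5, seed = 13))
  ds <- degree_stats(g)
  kappa1 <- ds$mean_k2 / ds$mean_k - 1
  lm <- nb_leading(g)$leading_eigenvalue
  expect_lt(abs(lm - kappa1) / kappa1, 0.05)
})

test_that("spectral orderings hold on every test graph", {
  suite <- c(fixture_suite(), random_config_suite(5, 150, master_seed = 30))
  for (g in suite) {
    ds <- degree_stats(g)
    la <- adjacency_leading(g)$leading_eigenvalue
    lm <- nb_leading(g)$leading_eigenvalue
    expect_lte(lm, la + 1e-8)                       # Lambda_M <= Lambda_A
    expect_gte(la, sqrt(ds$k_max) - 1e-8)
    expect_gte(la, ds$mean_k - 1e-8)
  }
})

test_that("localization classification separates hubs from k-cores", {
  # star(100): Lambda_A = 10 = sqrt(k_max) exactly -> hub-localized
  loc <- classify_localization(graph_fixture("star", n = 100))
  expect_equal(loc$label, "LHN")
  expect_equal(loc$lambda_A, loc$sqrt_kmax, tolerance = 1e-9)

  # regular graphs: Lambda_A = k = <k^2>/<k> -> k-core proxy at distance 0
  loc <- classify_localization(graph_fixture("regular", n = 20, k = 4, seed = 1))
  expect_equal(loc$label, "LKN")
  expect_equal(loc$lambda_A, loc$kappa_ratio, tolerance = 1e-9)

  # totality
  for (g in random_config_suite(4, 120, master_seed = 40)) {
    expect_true(classify_localization(g)$label %in% c("LHN", "LKN"))
  }
})
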