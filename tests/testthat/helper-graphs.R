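# Shared fixtures for the test suite: small graphs with closed-form spectra
# plus a reproducible batch of random configuration networks.

fixture_suite <- function() {
  list(
    k4 = graph_fixture("clique", n = 4),
    k6 = graph_fixture("clique", n = 6),
    cycle5 = graph_fixture("cycle", n = 5),
    cycle6 = graph_fixture("cycle", n = 6),
    regular4 = graph_fixture("regular", n = 10, k = 4, seed = 1),
    regular6 = graph_fixture("regular", n = 30, k = 6, seed = 2),
    two_cliques = graph_fixture("two_cliques_bridged", n = 5),
    k4_minus_edge = igraph::delete_edges(igraph::make_full_graph(4), 1)
  )
}

# Small random configuration networks, connected and cyclic, for property
# loops. Deterministic given the master seed.
random_config_suite <- function(n_graphs = 20, n_nodes = 150, master_seed = 100) {
  lapply(seq_len(n_graphs), function(i) {
    g <- generate_configuration_network(n_nodes, 2.5, seed = master_seed + i)
    giant_component(g)
  })
}

path_graph <- function(n) {
  igraph::make_graph(edges = rep(seq_len(n), each = 2)[-c(1, 2 * n)],
                     directed = FALSE)
}

write_temp_edges <- function(graph) {
  f <- tempfile(fileext = ".edges")
  write_edge_list(graph, f)
  f
}

cli_script <- function() {
  system.file("scripts", "epinet.R", package = "epithreshold")
}

run_cli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  res <- suppressWarnings(system2(
    rscript, c(cli_script(), args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(output = res, status = attr(res, "status") %||% 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
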