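#' Read an undirected simple graph from a whitespace-separated edge list
#'
#' Each non-comment line names one edge by its two endpoint labels; any
#' further tokens (e.g. weights) are ignored. Duplicate edges, reversed
#' duplicates and self-loops are dropped. Labels may be arbitrary strings and
#' are mapped to contiguous internal IDs in order of first appearance; the
#' original labels are kept in the vertex attribute \code{"name"}.
#'
#' @param path Path to the edge-list file. Lines starting with \code{#} are
#'   comments.
#' @return A simple undirected \code{igraph} graph.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("empty edge-list file: ", path)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0) {
    stop(sprintf("malformed edge-list line %d in %s: need two tokens", idx[bad[1]], path))
  }
  ends <- t(vapply(toks, function(x) x[1:2], character(2)))
  labels <- unique(as.vector(t(ends)))        # order of first appearance
  u <- match(ends[, 1], labels)
  v <- match(ends[, 2], labels)
  g <- igraph::graph_from_edgelist(cbind(u, v), directed = FALSE)
  igraph::V(g)$name <- labels
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a graph as a plain edge list
#'
#' One \code{"u v"} pair per line with 0-based integer node IDs, the format
#' \code{\link{read_edge_list}} reads back.
#'
#' @param graph An \code{igraph} graph.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = FALSE) - 1L
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Giant connected component
#'
#' Induced subgraph on the largest connected component, relabeled to
#' contiguous IDs. Ties in component size are broken in favour of the
#' component containing the smallest original node index.
#'
#' @param graph An \code{igraph} graph.
#' @return The giant component as an \code{igraph} graph.
#' @export
giant_component <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  comp <- igraph::components(graph)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    first_node <- vapply(best, function(b) min(which(comp$membership == b)), 1L)
    best <- best[which.min(first_node)]
  }
  igraph::induced_subgraph(graph, which(comp$membership == best))
}

#' First and second degree moments
#'
#' @param graph An \code{igraph} graph.
#' @return List with \code{mean_k} = \eqn{\langle k\rangle},
#'   \code{mean_k2} = \eqn{\langle k^2\rangle}, \code{k_min}, \code{k_max}.
#' @export
degree_stats <- function(graph) {
  d <- igraph::degree(graph)
  list(mean_k = mean(d), mean_k2 = mean(d^2),
       k_min = min(d), k_max = max(d))
}

#' Degree assortativity (Pearson degree-degree correlation)
#'
#' Pearson correlation of the degrees at the two ends of each edge, each edge
#' counted in both orientations (the standard Newman estimator). On graphs
#' with zero endpoint-degree variance (e.g. regular graphs) the coefficient
#' is undefined; \code{NA} is returned with a warning rather than a silent
#' \code{NaN}.
#'
#' @param graph An \code{igraph} graph with >= 2 edges.
#' @return Assortativity in [-1, 1], or \code{NA} if undefined.
#' @export
net_assortativity <- function(graph) {
  stopifnot(igraph::ecount(graph) >= 2)
  d <- igraph::degree(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  x <- c(d[el[, 1]], d[el[, 2]])
  y <- c(d[el[, 2]], d[el[, 1]])
  if (stats::var(x) == 0) {
    warning("assortativity undefined: zero degree variance at edge endpoints")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Average local clustering coefficient
#'
#' Mean of the Watts-Strogatz local clustering coefficients over all nodes;
#' nodes of degree < 2 contribute 0. The global transitivity (triangle
#' density) is attached as attribute \code{"transitivity"} for diagnostics.
#'
#' @param graph An \code{igraph} graph.
#' @return Average local clustering in [0, 1].
#' @export
net_clustering <- function(graph) {
  cc <- igraph::transitivity(graph, type = "localaverage", isolates = "zero")
  if (is.nan(cc)) cc <- 0
  glob <- igraph::transitivity(graph, type = "global")
  attr(cc, "transitivity") <- if (is.nan(glob)) 0 else glob
  cc
}

#' Modularity of a greedy community partition
#'
#' Newman-Girvan modularity Q of the partition found by deterministic greedy
#' modularity maximization (fast-greedy agglomeration). The partition, the
#' algorithm name and the seed are reported alongside Q so the value is
#' reproducible.
#'
#' @param graph A connected \code{igraph} graph with >= 1 edge.
#' @param seed RNG seed (the greedy agglomeration itself is deterministic;
#'   the seed is fixed regardless so the contract holds for any backend).
#' @return List with \code{Q}, \code{membership}, \code{algorithm},
#'   \code{seed}.
#' @export
net_modularity <- function(graph, seed = 1) {
  stopifnot(igraph::ecount(graph) >= 1)
  set.seed(seed)
  comm <- igraph::cluster_fast_greedy(graph)
  list(Q = igraph::modularity(comm),
       membership = igraph::membership(comm),
       algorithm = "fast_greedy", seed = seed)
}

#' Maximum k-core index
#'
#' Largest k for which the k-core (maximal subgraph of minimum degree k) is
#' non-empty, via iterative degree pruning.
#'
#' @param graph An \code{igraph} graph.
#' @return Integer core index.
#' @export
max_kcore <- function(graph) {
  max(igraph::coreness(graph))
}

#' Structural covariates of one network as a single row
#'
#' Assembles the metrics used to stratify prediction errors: size, degree
#' moments, assortativity r, average clustering c, modularity Q of a greedy
#' partition, and the maximum k-core index.
#'
#' @param graph An \code{igraph} graph (ideally a giant component).
#' @param name Network identifier for the row.
#' @param seed Seed forwarded to \code{\link{net_modularity}}.
#' @return One-row \code{data.frame} with columns name, N, E, mean_k,
#'   mean_k2, kmax, r, c, Q, kcore_max.
#' @export
structure_metrics <- function(graph, name = "network", seed = 1) {
  ds <- degree_stats(graph)
  r <- tryCatch(suppressWarnings(net_assortativity(graph)),
                error = function(e) NA_real_)
  data.frame(
    name = name,
    N = igraph::vcount(graph),
    E = igraph::ecount(graph),
    mean_k = ds$mean_k,
    mean_k2 = ds$mean_k2,
    kmax = ds$k_max,
    r = r,
    c = as.numeric(net_clustering(graph)),
    Q = net_modularity(graph, seed = seed)$Q,
    kcore_max = max_kcore(graph),
    stringsAsFactors = FALSE
  )
}
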