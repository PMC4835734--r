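#' Sample a power-law degree sequence
#'
#' Draws \code{n} node degrees i.i.d. from the truncated discrete power law
#' \eqn{P(k) \propto k^{-\nu_D}} on \code{k_min..k_max}. If the resulting sum
#' is odd, the last entry is redrawn until the sum is even, so a valid stub
#' matching exists.
#'
#' The defaults reproduce the uncorrelated scale-free ensemble used throughout
#' the package: minimum degree 3 and the structural cutoff
#' \code{k_max = floor(sqrt(n))}, which suppresses degree-degree correlations
#' in large networks.
#'
#' @param n Number of nodes (>= 10).
#' @param exponent Degree exponent \eqn{\nu_D > 1}.
#' @param k_min Minimum degree.
#' @param k_max Maximum degree; default the structural cutoff
#'   \code{floor(sqrt(n))}.
#' @param seed Integer RNG seed; the sequence is reproducible given the seed.
#' @return Integer vector of degrees with even sum.
#' @examples
#' d <- sample_degree_sequence(1000, 2.5, seed = 1)
#' sum(d) %% 2
#' @export
sample_degree_sequence <- function(n, exponent, k_min = 3,
                                   k_max = floor(sqrt(n)), seed = NULL) {
  stopifnot(n >= 10, exponent > 1, k_min >= 1, k_min <= k_max, k_max < n)
  if (!is.null(seed)) set.seed(seed)
  support <- k_min:k_max
  prob <- support^(-exponent)
  draw <- function(size) {
    if (length(support) == 1L) rep(support, size)
    else sample(support, size, replace = TRUE, prob = prob)
  }
  degs <- draw(n)
  if (sum(degs) %% 2L == 1L) {
    if (k_min == k_max) {
      stop("degree sum parity cannot be fixed: single-valued support with odd total")
    }
    # redraw one entry until the total is even
    repeat {
      degs[n] <- draw(1L)
      if (sum(degs) %% 2L == 0L) break
    }
  }
  as.integer(degs)
}

#' Analytic mean of the truncated power-law degree distribution
#'
#' Direct summation of \eqn{\sum_k k P(k)} over the finite support; used as
#' the closed-form reference for the sampler.
#'
#' @inheritParams sample_degree_sequence
#' @param moment Power of k to average (1 for the mean, 2 for the second
#'   moment).
#' @return The exact moment of the normalized truncated distribution.
#' @export
power_law_moment <- function(exponent, k_min, k_max, moment = 1) {
  k <- k_min:k_max
  p <- k^(-exponent)
  p <- p / sum(p)
  sum(k^moment * p)
}

#' Build a configuration-model network from a degree sequence
#'
#' Uniform stub matching followed by removal of self-loops and collapse of
#' multi-edges, so the returned graph is always simple and undirected.
#' Realized degrees can therefore fall slightly short of the request; the
#' number of edges lost to simplification is recorded in the graph attribute
#' \code{"removed_edges"}.
#'
#' @param degrees Integer degree sequence with even sum.
#' @param seed Integer RNG seed.
#' @return A simple undirected \code{igraph} graph.
#' @examples
#' g <- build_configuration_network(sample_degree_sequence(500, 2.5, seed = 1), seed = 2)
#' igraph::graph_attr(g, "removed_edges")
#' @export
build_configuration_network <- function(degrees, seed = NULL) {
  stopifnot(length(degrees) >= 2, all(degrees >= 1))
  if (sum(degrees) %% 2L != 0L) stop("degree sum must be even for stub matching")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_degseq(degrees, method = "configuration")
  requested <- sum(degrees) / 2
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::graph_attr(g, "removed_edges") <- requested - igraph::ecount(g)
  g
}

#' Generate an uncorrelated configuration network in one call
#'
#' Convenience wrapper: power-law degree sequence at the structural cutoff,
#' then stub matching. This is the synthetic ensemble the threshold
#' comparison assumes.
#'
#' @inheritParams sample_degree_sequence
#' @return A simple undirected \code{igraph} graph.
#' @export
generate_configuration_network <- function(n, exponent, k_min = 3,
                                           k_max = floor(sqrt(n)), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  degs <- sample_degree_sequence(n, exponent, k_min, k_max)
  build_configuration_network(degs)
}

#' Tune degree-degree correlations by degree-preserving rewiring
#'
#' Greedy double-edge swaps in the style of Xulvi-Brunet and Sokolov: two
#' edges are picked uniformly at random, their endpoints re-paired, and the
#' swap accepted when it moves the Pearson degree-degree correlation strictly
#' toward \code{target_r} while keeping the graph simple. The degree sequence
#' is preserved exactly.
#'
#' Because only the cross-moment of degrees at edge endpoints changes under a
#' swap, the assortativity update is O(1) per proposal.
#'
#' @param graph A simple undirected \code{igraph} graph with >= 2 edges and
#'   non-constant endpoint degrees.
#' @param target_r Target assortativity in (-1, 1).
#' @param max_sweeps Proposal budget in sweeps of \code{ecount(graph)}
#'   proposals each.
#' @param tol Stop when \code{|r - target_r| <= tol}.
#' @param seed Integer RNG seed.
#' @return The rewired graph, with attributes \code{"assortativity_achieved"}
#'   and \code{"rewire_converged"}. If the target is unreachable within the
#'   budget the best-effort graph is returned with a warning.
#' @export
rewire_assortativity <- function(graph, target_r, max_sweeps = 100,
                                 tol = 0.01, seed = NULL) {
  stopifnot(igraph::ecount(graph) >= 2, abs(target_r) < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(graph)
  d <- igraph::degree(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  m <- nrow(el)

  # oriented endpoint-degree sums; Sx and Sxx depend only on the degree
  # sequence and are invariant under double-edge swaps
  M <- 2 * m
  Sx <- sum(d[el[, 1]] + d[el[, 2]])
  Sxx <- sum(d[el[, 1]]^2 + d[el[, 2]]^2)
  Sxy <- 2 * sum(d[el[, 1]] * d[el[, 2]])
  varx <- Sxx / M - (Sx / M)^2
  if (varx <= .Machine$double.eps * (Sx / M)^2) {
    stop("assortativity undefined: zero degree variance at edge endpoints")
  }
  r_of <- function(sxy) (sxy / M - (Sx / M)^2) / varx
  r0 <- r_of(Sxy)
  if (abs(r0 - target_r) <= tol) {
    igraph::graph_attr(graph, "assortativity_achieved") <- r0
    igraph::graph_attr(graph, "rewire_converged") <- TRUE
    return(graph)
  }
  target_Sxy <- (target_r * varx + (Sx / M)^2) * M

  ekey <- function(u, v) ifelse(u < v, u * n + v, v * n + u)
  edge_set <- new.env(hash = TRUE, size = 2L * m)
  for (i in seq_len(m)) assign(as.character(ekey(el[i, 1], el[i, 2])), TRUE, envir = edge_set)

  budget <- max_sweeps * m
  converged <- FALSE
  for (it in seq_len(budget)) {
    ij <- sample.int(m, 2L)
    e1 <- el[ij[1], ]; e2 <- el[ij[2], ]
    if (stats::runif(1) < 0.5) e2 <- rev(e2)       # random re-pairing orientation
    a <- e1[1]; b <- e1[2]; cc <- e2[1]; dd <- e2[2]
    # proposal: (a,b),(cc,dd) -> (a,cc),(b,dd)
    if (a == cc || b == dd) next
    k1 <- as.character(ekey(a, cc)); k2 <- as.character(ekey(b, dd))
    if (k1 == k2) next
    if (exists(k1, envir = edge_set, inherits = FALSE) ||
        exists(k2, envir = edge_set, inherits = FALSE)) next
    delta <- 2 * (d[a] * d[cc] + d[b] * d[dd] - d[a] * d[b] - d[cc] * d[dd])
    if (abs(Sxy + delta - target_Sxy) >= abs(Sxy - target_Sxy)) next
    rm(list = c(as.character(ekey(a, b)), as.character(ekey(cc, dd))), envir = edge_set)
    assign(k1, TRUE, envir = edge_set)
    assign(k2, TRUE, envir = edge_set)
    el[ij[1], ] <- c(a, cc)
    el[ij[2], ] <- c(b, dd)
    Sxy <- Sxy + delta
    if (abs(r_of(Sxy) - target_r) <= tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("rewiring stopped at r = %.4f without reaching target %.4f",
                    r_of(Sxy), target_r))
  }
  out <- igraph::graph_from_edgelist(el, directed = FALSE)
  out <- igraph::add_vertices(out, max(0L, n - igraph::vcount(out)))
  igraph::graph_attr(out, "assortativity_achieved") <- r_of(Sxy)
  igraph::graph_attr(out, "rewire_converged") <- converged
  out
}

#' Deterministic closed-form fixture graphs
#'
#' Small named graphs with known spectra and thresholds, used for exact
#' checks: \code{regular} (random k-regular, deterministic given seed),
#' \code{star} (K_{1,n}), \code{cycle}, \code{clique} (K_N) and
#' \code{two_cliques_bridged} (two K_m joined by a single edge).
#'
#' @param name One of \code{"regular"}, \code{"star"}, \code{"cycle"},
#'   \code{"clique"}, \code{"two_cliques_bridged"}.
#' @param n Node count (for \code{star}, the number of leaves; for
#'   \code{two_cliques_bridged}, the clique size).
#' @param k Degree, for \code{regular}.
#' @param seed RNG seed, used only by \code{regular}.
#' @return An \code{igraph} graph.
#' @export
graph_fixture <- function(name = c("regular", "star", "cycle", "clique",
                                   "two_cliques_bridged"),
                          n, k = NULL, seed = 1) {
  name <- match.arg(name)
  switch(name,
    regular = {
      stopifnot(!is.null(k), (n * k) %% 2 == 0)
      set.seed(seed)
      igraph::sample_k_regular(n, k)
    },
    star = igraph::make_star(n + 1, mode = "undirected", center = 1),
    cycle = igraph::make_ring(n),
    clique = igraph::make_full_graph(n),
    two_cliques_bridged = {
      g1 <- igraph::make_full_graph(n)
      g2 <- igraph::make_full_graph(n)
      g <- igraph::disjoint_union(g1, g2)
      igraph::add_edges(g, c(1, n + 1))
    }
  )
}
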