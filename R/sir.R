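# Compressed adjacency (0-based CSR) for the compiled simulator.
graph_csr <- function(graph) {
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  src <- c(el[, 1], el[, 2])
  dst <- c(el[, 2], el[, 1])
  o <- order(src)
  list(adj = as.integer(dst[o] - 1L),
       ptr = as.integer(c(0L, cumsum(tabulate(src, nbins = n)))),
       n = n)
}

#' One SIR realization (reference implementation with trajectory)
#'
#' Discrete-time synchronous-update SIR: one infected seed, all other nodes
#' susceptible; at each step every infected node transmits to each
#' susceptible neighbour independently with probability \code{beta}, then
#' recovers with probability \code{gamma} (a node may transmit and recover
#' in the same step; nodes infected at step t transmit from step t+1). The
#' epidemic stops when no infected nodes remain.
#'
#' This pure-R single run exists for auditing: it can return the full
#' S/I/R trajectory, and its dynamics are cross-checked statistically
#' against the compiled ensemble simulator used at scale.
#'
#' @param graph A connected \code{igraph} graph.
#' @param beta Per-contact per-step transmission probability in [0, 1].
#' @param gamma Per-step recovery probability in (0, 1].
#' @param seed_node Seed node index, or \code{"random"}.
#' @param seed Optional RNG seed.
#' @param trajectory If TRUE, attach a per-step data.frame of S/I/R counts.
#' @param order \code{"transmit-first"} (default: a node transmits, then may
#'   recover, within one step) or \code{"recover-first"} (the recovery draw
#'   comes first and a recovering node does not transmit that step).
#' @return Final recovered fraction r in [1/N, 1]; with
#'   \code{trajectory = TRUE}, the attribute \code{"trajectory"} holds the
#'   S/I/R counts per step.
#' @export
run_sir <- function(graph, beta, gamma = 1, seed_node = "random",
                    seed = NULL, trajectory = FALSE,
                    order = c("transmit-first", "recover-first")) {
  order <- match.arg(order)
  stopifnot(beta >= 0, beta <= 1, gamma > 0, gamma <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- igraph::vcount(graph)
  adj <- igraph::as_adj_list(graph)
  status <- integer(n)                      # 0 S, 1 I, 2 R
  seed_node <- if (identical(seed_node, "random")) sample.int(n, 1) else as.integer(seed_node)
  status[seed_node] <- 1L
  infected <- seed_node
  traj <- list(c(S = n - 1L, I = 1L, R = 0L))
  while (length(infected) > 0) {
    recovers <- stats::runif(length(infected)) < gamma
    transmitters <- if (order == "recover-first") infected[!recovers] else infected
    newly <- integer(0)
    for (i in transmitters) {
      nb <- as.integer(adj[[i]])
      nb <- nb[status[nb] == 0L]
      hit <- nb[stats::runif(length(nb)) < beta]
      status[hit] <- 1L
      newly <- c(newly, hit)
    }
    status[infected[recovers]] <- 2L
    infected <- c(infected[!recovers], newly)
    traj[[length(traj) + 1]] <- c(S = sum(status == 0L), I = sum(status == 1L),
                                  R = sum(status == 2L))
  }
  r <- sum(status == 2L) / n
  if (trajectory) {
    tr <- do.call(rbind, traj)
    attr(r, "trajectory") <- data.frame(step = seq_len(nrow(tr)) - 1L, tr)
  }
  r
}

#' Ensemble of SIR final epidemic sizes
#'
#' Runs \code{n_realizations} independent SIR realizations with the
#' compiled synchronous-update simulator, each from its own uniformly
#' random seed node, and collects the final recovered fractions. The
#' transmission probability is \eqn{\beta = \lambda\gamma} and must not
#' exceed 1.
#'
#' @param graph A connected \code{igraph} graph.
#' @param lambda Effective spreading rate \eqn{\beta/\gamma}.
#' @param gamma Per-step recovery probability (default 1, the convention
#'   under which \eqn{\lambda = \beta}).
#' @param n_realizations Number of independent realizations.
#' @param seed Integer RNG seed; same seed, same ensemble.
#' @param order Within-step micro-order, see \code{\link{run_sir}}.
#' @return Object of class \code{"outbreak_ensemble"}: list with
#'   \code{final_sizes}, \code{n_realizations}, \code{N}, \code{lambda},
#'   \code{beta}, \code{gamma}, \code{order}.
#' @examples
#' g <- graph_fixture("regular", n = 100, k = 4, seed = 1)
#' ens <- run_sir_ensemble(g, lambda = 0.5, n_realizations = 50, seed = 1)
#' mean(ens$final_sizes)
#' @export
run_sir_ensemble <- function(graph, lambda, gamma = 1, n_realizations = 1e4,
                             seed = NULL,
                             order = c("transmit-first", "recover-first")) {
  order <- match.arg(order)
  beta <- lambda * gamma
  if (beta > 1 + 1e-12) stop("beta = lambda * gamma exceeds 1; not a probability")
  beta <- min(beta, 1)
  stopifnot(beta >= 0, gamma > 0, gamma <= 1, n_realizations >= 1)
  if (!is.null(seed)) set.seed(seed)
  csr <- graph_csr(graph)
  fs <- sir_final_sizes_cpp(csr$adj, csr$ptr, beta, gamma,
                            as.integer(n_realizations),
                            order == "recover-first")
  structure(list(final_sizes = fs,
                 n_realizations = as.integer(n_realizations),
                 N = csr$n, lambda = lambda, beta = beta, gamma = gamma,
                 order = order),
            class = "outbreak_ensemble")
}

#' @export
print.outbreak_ensemble <- function(x, ...) {
  cat(sprintf(
    "SIR final-size ensemble: N = %d, lambda = %.4g (beta = %.4g, gamma = %.4g)\n",
    x$N, x$lambda, x$beta, x$gamma))
  cat(sprintf("  %d realizations, mean r = %.4g, sd = %.4g\n",
              x$n_realizations, mean(x$final_sizes), stats::sd(x$final_sizes)))
  invisible(x)
}
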