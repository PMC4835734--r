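#' Estimate the SIR epidemic threshold of a network
#'
#' The package's main entry point. Fits all three theoretical threshold
#' predictors to a network — mean-field-like (degree moments), quenched
#' mean-field (adjacency spectral radius) and dynamical message passing
#' (non-backtracking spectral radius) — and, optionally, estimates the
#' numerical threshold by sweeping the relative-variance statistic
#' \eqn{\chi} of simulated SIR final-size ensembles over a spreading-rate
#' grid and locating its peak.
#'
#' The analysis runs on the giant connected component (a message reports
#' any reduction). Thresholds are expressed in the effective spreading rate
#' \eqn{\lambda = \beta/\gamma}.
#'
#' @param graph An \code{igraph} graph, or a path to a whitespace-separated
#'   edge-list file (read with \code{\link{read_edge_list}}).
#' @param gamma Per-step recovery probability in (0, 1].
#' @param numerical Estimate the simulation-based threshold as well?
#' @param lambda_grid Spreading-rate grid for the chi sweep; default a
#'   25-point geometric grid over [0.25, 4] times the MFL threshold.
#' @param n_realizations SIR realizations per grid point.
#' @param seed Master RNG seed for all stochastic stages.
#' @param name Network identifier used in printing and records.
#' @return Object of class \code{"epi_thresholds"} with components
#'   \code{thresholds} (mfl/qmf/dmp), \code{lambda_c} (numerical threshold
#'   or NA), \code{chi_curve}, \code{spectral_A}, \code{spectral_M},
#'   \code{localization}, \code{structure} (one-row metrics data.frame),
#'   \code{record} (full comparison row when numerical), \code{graph}.
#' @examples
#' g <- graph_fixture("regular", n = 200, k = 6, seed = 1)
#' fit <- epidemic_thresholds(g, numerical = FALSE)
#' coef(fit)
#' @export
epidemic_thresholds <- function(graph, gamma = 1, numerical = TRUE,
                                lambda_grid = NULL, n_realizations = 2000,
                                seed = 1, name = "network") {
  if (is.character(graph)) {
    name <- if (identical(name, "network")) basename(graph) else name
    graph <- read_edge_list(graph)
  }
  stopifnot(inherits(graph, "igraph"), gamma > 0, gamma <= 1)
  g <- giant_component(graph)
  if (igraph::vcount(g) < igraph::vcount(graph)) {
    message(sprintf("analysis restricted to the giant component: %d of %d nodes",
                    igraph::vcount(g), igraph::vcount(graph)))
  }
  spectral_A <- adjacency_leading(g)
  spectral_M <- tryCatch(nb_leading(g), error = function(e) NULL)
  th <- predict_thresholds(g, spectral_A, spectral_M)
  loc <- classify_localization(g, spectral_A)
  sm <- structure_metrics(g, name = name, seed = seed)

  curve <- NULL
  lambda_c <- NA_real_
  record <- NULL
  if (numerical) {
    if (is.null(lambda_grid)) {
      lambda_grid <- default_lambda_grid(th$mfl, gamma = gamma)
    }
    curve <- sweep_chi(g, lambda_grid, gamma = gamma,
                       n_realizations = n_realizations, seed = seed)
    lambda_c <- suppressWarnings(numerical_threshold(curve))
    record <- build_record(g, name, lambda_c, thresholds = th,
                           spectral_A = spectral_A, spectral_M = spectral_M,
                           seed = seed)
  }
  structure(list(name = name, graph = g, gamma = gamma,
                 thresholds = th, lambda_c = lambda_c, chi_curve = curve,
                 spectral_A = spectral_A, spectral_M = spectral_M,
                 localization = loc, structure = sm, record = record,
                 n_realizations = n_realizations, seed = seed),
            class = "epi_thresholds")
}

#' @export
print.epi_thresholds <- function(x, ...) {
  cat(sprintf("SIR epidemic thresholds for '%s' (N = %d, E = %d)\n",
              x$name, x$structure$N, x$structure$E))
  cat(sprintf("  MFL (degree moments):     lambda_c = %.4f\n", x$thresholds$mfl))
  cat(sprintf("  QMF (adjacency spectrum): lambda_c = %.4f\n", x$thresholds$qmf))
  if (x$thresholds$dmp_defined) {
    flag <- if (x$thresholds$dmp_no_transition) "  [no transition in beta <= 1]" else ""
    cat(sprintf("  DMP (non-backtracking):   lambda_c = %.4f%s\n",
                x$thresholds$dmp, flag))
  } else {
    cat("  DMP (non-backtracking):   undefined (tree: no cycle)\n")
  }
  if (!is.na(x$lambda_c)) {
    b <- if (isTRUE(attr(x$lambda_c, "boundary"))) " [peak at grid endpoint]" else ""
    cat(sprintf("  numerical (chi peak):     lambda_c = %.4f%s\n",
                as.numeric(x$lambda_c), b))
  }
  invisible(x)
}

#' @export
summary.epi_thresholds <- function(object, ...) {
  print(object)
  s <- object$structure
  cat(sprintf("\nStructure: <k> = %.3f, <k^2> = %.2f, k_max = %d, max k-core = %d\n",
              s$mean_k, s$mean_k2, s$kmax, s$kcore_max))
  cat(sprintf("  assortativity r = %s, clustering c = %.4f, modularity Q = %.4f\n",
              ifelse(is.na(s$r), "undefined", sprintf("%.4f", s$r)), s$c, s$Q))
  loc <- object$localization
  cat(sprintf("Localization: %s (Lambda_A = %.3f vs sqrt(k_max) = %.3f, <k^2>/<k> = %.3f)%s\n",
              loc$label, loc$lambda_A, loc$sqrt_kmax, loc$kappa_ratio,
              if (loc$tie) " [tie]" else ""))
  cat(sprintf("  IPR(adjacency) = %.4g%s\n", object$spectral_A$ipr,
              if (!is.null(object$spectral_M))
                sprintf(", IPR(non-backtracking) = %.4g", object$spectral_M$ipr)
              else ""))
  if (!is.null(object$record)) {
    r <- object$record
    cat(sprintf("\nErrors vs numerical threshold %.4f (closest: %s%s)\n",
                r$lambda_c, r$closest_method, if (r$closest_tie) ", tie" else ""))
    cat(sprintf("  MFL: abs %.4f rel %.3f | QMF: abs %.4f rel %.3f | DMP: abs %s rel %s\n",
                r$abs_err_mfl, r$rel_err_mfl, r$abs_err_qmf, r$rel_err_qmf,
                ifelse(is.na(r$abs_err_dmp), "NA", sprintf("%.4f", r$abs_err_dmp)),
                ifelse(is.na(r$rel_err_dmp), "NA", sprintf("%.3f", r$rel_err_dmp))))
  }
  invisible(object)
}

#' @export
coef.epi_thresholds <- function(object, ...) {
  c(mfl = object$thresholds$mfl,
    qmf = object$thresholds$qmf,
    dmp = object$thresholds$dmp,
    numerical = as.numeric(object$lambda_c))
}

#' @export
plot.epi_thresholds <- function(x, ...) {
  if (is.null(x$chi_curve)) {
    stop("no chi curve: refit with numerical = TRUE to plot")
  }
  plot(x$chi_curve, ...)
  th <- x$thresholds
  graphics::abline(v = c(th$mfl, th$qmf, th$dmp),
                   col = c("black", "red", "blue"), lty = 3)
  graphics::legend("topright", bty = "n", lty = c(3, 3, 3, 2),
                   col = c("black", "red", "blue", "grey40"),
                   legend = c("MFL", "QMF", "DMP", "numerical"))
  invisible(x)
}

#' Simulate final epidemic sizes from a fitted threshold object
#'
#' Draws new SIR final-size ensembles on the fitted network, by default at
#' the estimated numerical threshold.
#'
#' @param object An \code{\link{epidemic_thresholds}} fit.
#' @param nsim Number of realizations.
#' @param seed RNG seed.
#' @param lambda Spreading rate; defaults to the numerical threshold (or
#'   the MFL prediction when no numerical fit was made).
#' @param ... Unused.
#' @return Numeric vector of final recovered fractions.
#' @export
simulate.epi_thresholds <- function(object, nsim = 1000, seed = NULL,
                                    lambda = NULL, ...) {
  if (is.null(lambda)) {
    lambda <- if (!is.na(object$lambda_c)) as.numeric(object$lambda_c)
              else object$thresholds$mfl
  }
  ens <- run_sir_ensemble(object$graph, lambda, gamma = object$gamma,
                          n_realizations = nsim, seed = seed)
  ens$final_sizes
}
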