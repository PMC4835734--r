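#' Mean-field-like (degree-moment) epidemic threshold
#'
#' \eqn{\lambda_c^{MFL} = \langle k\rangle / (\langle k^2\rangle - \langle
#' k\rangle)}: the SIR threshold predicted from the degree distribution
#' alone (heterogeneous mean-field / percolation value).
#'
#' @param stats Degree moments from \code{\link{degree_stats}}, or an
#'   \code{igraph} graph.
#' @return Threshold in the effective spreading rate \eqn{\lambda = \beta/\gamma}.
#' @examples
#' mfl_threshold(graph_fixture("cycle", n = 6))  # 2/(4-2) = 1
#' @export
mfl_threshold <- function(stats) {
  if (inherits(stats, "igraph")) stats <- degree_stats(stats)
  if (stats$mean_k2 <= stats$mean_k) {
    stop("MFL threshold undefined: <k^2> <= <k>")
  }
  stats$mean_k / (stats$mean_k2 - stats$mean_k)
}

#' Quenched mean-field epidemic threshold
#'
#' \eqn{\lambda_c^{QMF} = 1/\Lambda_A}, the reciprocal of the adjacency
#' spectral radius.
#'
#' @param lambda_A Leading adjacency eigenvalue (> 0), or an \code{igraph}
#'   graph from which it is computed.
#' @return Threshold in \eqn{\lambda}.
#' @export
qmf_threshold <- function(lambda_A) {
  if (inherits(lambda_A, "igraph")) {
    lambda_A <- adjacency_leading(lambda_A)$leading_eigenvalue
  }
  stopifnot(lambda_A > 0)
  1 / lambda_A
}

#' Dynamical message-passing epidemic threshold
#'
#' \eqn{\lambda_c^{DMP} = 1/\Lambda_M}, the reciprocal of the leading
#' non-backtracking eigenvalue. When \eqn{\Lambda_M \le 1} the value is
#' >= 1 and lies outside the admissible spreading range (\eqn{\beta \le 1}
#' at \eqn{\gamma = 1}); the result then carries the attribute
#' \code{"no_transition" = TRUE}.
#'
#' @param lambda_M Leading non-backtracking eigenvalue (> 0), or an
#'   \code{igraph} graph from which it is computed (trees raise the
#'   no-cycle error of \code{\link{nb_leading}}).
#' @return Threshold in \eqn{\lambda}, possibly flagged.
#' @export
dmp_threshold <- function(lambda_M) {
  if (inherits(lambda_M, "igraph")) {
    lambda_M <- nb_leading(lambda_M)$leading_eigenvalue
  }
  stopifnot(lambda_M > 0)
  out <- 1 / lambda_M
  if (lambda_M <= 1 + 1e-8) attr(out, "no_transition") <- TRUE
  out
}

#' All three theoretical thresholds for one network
#'
#' Convenience assembly of the MFL, QMF and DMP predictors. The DMP entry is
#' \code{NA} on trees (no cycle) with \code{dmp_defined = FALSE}.
#'
#' Thresholds are expressed in the effective spreading rate
#' \eqn{\lambda = \beta/\gamma}; simulations in this package follow the
#' \eqn{\gamma = 1} convention, under which \eqn{\lambda = \beta}.
#'
#' @param graph A connected \code{igraph} graph.
#' @param spectral_A Optional precomputed \code{\link{adjacency_leading}}.
#' @param spectral_M Optional precomputed \code{\link{nb_leading}}.
#' @return List with \code{mfl}, \code{qmf}, \code{dmp},
#'   \code{dmp_defined}, \code{dmp_no_transition}.
#' @export
predict_thresholds <- function(graph, spectral_A = NULL, spectral_M = NULL) {
  if (is.null(spectral_A)) spectral_A <- adjacency_leading(graph)
  dmp <- NA_real_
  dmp_defined <- FALSE
  no_transition <- FALSE
  lm_try <- if (is.null(spectral_M)) {
    tryCatch(nb_leading(graph), error = function(e) e)
  } else spectral_M
  if (inherits(lm_try, "spectral_summary")) {
    d <- dmp_threshold(lm_try$leading_eigenvalue)
    no_transition <- isTRUE(attr(d, "no_transition"))
    dmp <- as.numeric(d)
    dmp_defined <- TRUE
  } else if (!grepl("no cycle", conditionMessage(lm_try))) {
    stop(lm_try)
  }
  list(mfl = mfl_threshold(graph),
       qmf = qmf_threshold(spectral_A$leading_eigenvalue),
       dmp = dmp,
       dmp_defined = dmp_defined,
       dmp_no_transition = no_transition)
}
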