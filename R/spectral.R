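#' Inverse participation ratio of a vector
#'
#' \eqn{\mathrm{IPR} = \sum_i v_i^4} after L2 normalization: 1/N for a
#' uniform (delocalized) vector, 1 for a one-hot (fully localized) vector.
#'
#' @param v Nonzero numeric vector.
#' @return IPR in [1/length(v), 1].
#' @export
ipr <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("IPR undefined for the zero vector")
  sum((v / nrm)^4)
}

new_spectral_summary <- function(kind, value, vector) {
  structure(list(matrix_kind = kind,
                 leading_eigenvalue = value,
                 principal_vector = vector,
                 ipr = ipr(vector)),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("Leading eigenpair of the %s matrix\n", x$matrix_kind))
  cat(sprintf("  eigenvalue: %.6g   IPR: %.4g   (N = %d)\n",
              x$leading_eigenvalue, x$ipr, length(x$principal_vector)))
  invisible(x)
}

# Fix the Perron vector's sign, check nonnegativity, and L2-normalize.
as_perron_vector <- function(v, tol = 1e-6) {
  s <- sign(v[which.max(abs(v))])
  v <- v * s
  if (min(v) < -tol * max(abs(v))) {
    stop("leading eigenvector is not sign-consistent; eigensolver did not ",
         "converge to the Perron vector")
  }
  v <- pmax(v, 0)
  v / sqrt(sum(v^2))
}

# Dense path below this many matrix rows; iterative (ARPACK) above.
.DENSE_LIMIT <- 600L

#' Leading adjacency eigenpair
#'
#' Largest eigenvalue \eqn{\Lambda_A} of the 0/1 adjacency matrix and its
#' Perron eigenvector, by dense symmetric eigendecomposition for small
#' graphs and a sparse Lanczos/Arnoldi iteration otherwise.
#'
#' @param graph A connected \code{igraph} graph with >= 2 nodes.
#' @param tol Convergence tolerance on the eigenvalue.
#' @param maxiter Iteration cap for the sparse solver.
#' @return A \code{spectral_summary}: \code{leading_eigenvalue},
#'   unit-norm nonnegative \code{principal_vector}, \code{ipr}.
#' @examples
#' adjacency_leading(graph_fixture("star", n = 4))$leading_eigenvalue  # sqrt(4)
#' @export
adjacency_leading <- function(graph, tol = 1e-10, maxiter = 1e4) {
  n <- igraph::vcount(graph)
  stopifnot(n >= 2)
  if (!igraph::is_connected(graph)) stop("graph must be connected")
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  if (n <= .DENSE_LIMIT) {
    e <- eigen(as.matrix(A), symmetric = TRUE)
    val <- e$values[1]
    vec <- e$vectors[, 1]
  } else {
    res <- igraph::arpack(function(x, extra) as.numeric(A %*% x),
                          sym = TRUE,
                          options = list(n = n, nev = 1, ncv = 20,
                                         which = "LA", maxiter = maxiter,
                                         tol = tol))
    val <- res$values[1]
    vec <- if (is.matrix(res$vectors)) res$vectors[, 1] else res$vectors
    vec <- as.numeric(vec)
  }
  new_spectral_summary("adjacency", val, as_perron_vector(vec))
}

#' Non-backtracking matrix as a sparse 2N x 2N block companion matrix
#'
#' The block matrix \eqn{[[A, I - D], [I, 0]]}, with A the adjacency matrix
#' and D the degree diagonal, whose non-trivial spectrum equals that of the
#' 2E x 2E directed-edge non-backtracking operator. Returned as a sparse
#' \code{Matrix} so it is never densified at scale.
#'
#' @param graph A simple undirected \code{igraph} graph.
#' @return A sparse \code{dgCMatrix} of dimension 2N x 2N.
#' @export
nb_matrix <- function(graph) {
  n <- igraph::vcount(graph)
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  d <- igraph::degree(graph)
  top <- cbind(A, Matrix::Diagonal(n, 1 - d))
  bottom <- cbind(Matrix::Diagonal(n), Matrix::Matrix(0, n, n, sparse = TRUE))
  methods::as(rbind(top, bottom), "CsparseMatrix")
}

# Select the Perron eigenvalue from a (possibly complex) spectrum: the
# largest-magnitude eigenvalue, which for a nonnegative operator is real.
# Defective eigenvalues (Jordan blocks, e.g. on cycles) split numerically
# into conjugate pairs with imaginary parts ~sqrt(machine eps), so the
# reality assertion uses a 1e-6 tolerance; the returned real part is
# accurate to much better than that.
select_perron <- function(values, imag_tol = 1e-6) {
  mags <- Mod(values)
  mx <- max(mags)
  # window wide enough that a defective pair split by ~sqrt(machine eps)
  # does not mask an equal-magnitude Perron root
  cand <- which(mags >= mx * (1 - 1e-6) - 1e-12)
  real_cand <- cand[abs(Im(values[cand])) <= imag_tol * max(1, mx)]
  if (length(real_cand) == 0) {
    stop("leading non-backtracking eigenvalue is not real within tolerance; ",
         "largest-magnitude eigenvalue ", format(values[cand[1]]))
  }
  # the Perron root of a nonnegative operator: real and positive
  best <- real_cand[which.max(Re(values[real_cand]))]
  val <- Re(values[best])
  # a defective Perron root splits into a pair straddling the true value by
  # ~sqrt(machine eps); averaging the cluster cancels the leading error
  cluster <- values[Mod(values - val) <= 1e-6 * max(1, mx)]
  if (length(cluster) > 1) val <- mean(Re(cluster))
  list(index = best, value = val)
}

#' Leading non-backtracking eigenpair
#'
#' Largest-magnitude eigenvalue \eqn{\Lambda_M} of the non-backtracking
#' block matrix (real and >= 1 on connected graphs with a cycle, by
#' Perron-Frobenius on the edge representation), together with the
#' node-space non-backtracking centrality: the first N components of the
#' 2N eigenvector, sign-fixed nonnegative and unit-normalized.
#'
#' Trees are rejected: non-backtracking walks on a tree die out and the
#' threshold based on \eqn{1/\Lambda_M} is undefined.
#'
#' @inheritParams adjacency_leading
#' @return A \code{spectral_summary} for the non-backtracking matrix.
#' @examples
#' nb_leading(graph_fixture("clique", n = 4))$leading_eigenvalue  # k - 1 = 2
#' @export
nb_leading <- function(graph, tol = 1e-10, maxiter = 1e4) {
  n <- igraph::vcount(graph)
  if (!igraph::is_connected(graph)) stop("graph must be connected")
  if (igraph::ecount(graph) < n) {
    stop("no cycle: the non-backtracking spectrum of a tree is trivial and ",
         "the DMP threshold is undefined")
  }
  M <- nb_matrix(graph)
  if (2 * n <= .DENSE_LIMIT) {
    e <- eigen(as.matrix(M), only.values = TRUE)
    sel <- select_perron(e$values)
  } else {
    res <- igraph::arpack(function(x, extra) as.numeric(M %*% x),
                          sym = FALSE,
                          options = list(n = 2L * n, nev = 4, ncv = 30,
                                         which = "LM", maxiter = maxiter,
                                         tol = tol))
    sel <- select_perron(res$values)
  }
  mu <- sel$value
  # Node-space non-backtracking centrality: the first-N block x1 of the 2N
  # eigenvector satisfies the *symmetric* eigenproblem
  #   (A - (D - I)/mu) x1 = mu x1,
  # and mu + max(d-1)/mu is the Perron value of that shifted nonnegative
  # matrix, so x1 is its well-conditioned leading eigenvector. Extracting it
  # this way avoids the generalized-vector contamination a defective block
  # eigenvalue (e.g. on cycles) injects into the 2N eigenvector.
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  d <- igraph::degree(graph)
  H <- A - Matrix::Diagonal(n, (d - 1) / mu)
  if (n <= .DENSE_LIMIT) {
    x1 <- eigen(as.matrix(H), symmetric = TRUE)$vectors[, 1]
  } else {
    res_h <- igraph::arpack(function(x, extra) as.numeric(H %*% x),
                            sym = TRUE,
                            options = list(n = n, nev = 1, ncv = 20,
                                           which = "LA", maxiter = maxiter,
                                           tol = tol))
    x1 <- if (is.matrix(res_h$vectors)) res_h$vectors[, 1] else res_h$vectors
    x1 <- as.numeric(x1)
  }
  new_spectral_summary("nonbacktracking", mu, as_perron_vector(x1))
}

#' Dense directed-edge non-backtracking oracle
#'
#' Builds the explicit 2E x 2E non-backtracking matrix — entry 1 for
#' directed-edge pairs (i->j),(j->l) with l != i — and returns its leading
#' eigenvalue by dense eigendecomposition. Exists as an independent check of
#' the block-matrix computation and is capped to small graphs.
#'
#' @param graph A simple undirected \code{igraph} graph with <= 2000 edges.
#' @return The leading (largest-magnitude) eigenvalue, a real scalar.
#' @export
nb_edge_oracle <- function(graph) {
  m <- igraph::ecount(graph)
  stopifnot(m >= 1)
  if (m > 2000) stop("edge-space oracle capped at 2000 edges")
  el <- igraph::as_edgelist(graph, names = FALSE)
  tails <- c(el[, 1], el[, 2])
  heads <- c(el[, 2], el[, 1])
  ne <- 2L * m
  rev_of <- c((m + 1):ne, 1:m)
  out_by_tail <- split(seq_len(ne), tails)
  B <- matrix(0, ne, ne)
  for (e in seq_len(ne)) {
    succ <- out_by_tail[[as.character(heads[e])]]
    succ <- succ[succ != rev_of[e]]
    B[e, succ] <- 1
  }
  vals <- eigen(B, only.values = TRUE)$values
  select_perron(vals)$value
}

#' Classify eigenvector localization: hub (LHN) vs k-core (LKN)
#'
#' A network is a localized-hub network (LHN) when the adjacency spectral
#' radius \eqn{\Lambda_A} is strictly closer to \eqn{\sqrt{k_{max}}} (the
#' hub-dominated value) than to \eqn{\langle k^2\rangle/\langle k\rangle}
#' (the k-core-dominated value), and a localized-k-core network (LKN)
#' otherwise. Exact ties go to LKN with a flag.
#'
#' @param graph A connected \code{igraph} graph.
#' @param adjacency Optional precomputed \code{\link{adjacency_leading}}
#'   result for \code{graph}.
#' @return List with \code{label} ("LHN"/"LKN"), \code{lambda_A},
#'   \code{sqrt_kmax}, \code{kappa_ratio}, \code{tie} flag.
#' @export
classify_localization <- function(graph, adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- adjacency_leading(graph)
  ds <- degree_stats(graph)
  lambda_A <- adjacency$leading_eigenvalue
  sqrt_kmax <- sqrt(ds$k_max)
  kappa <- ds$mean_k2 / ds$mean_k
  d_hub <- abs(lambda_A - sqrt_kmax)
  d_core <- abs(lambda_A - kappa)
  tie <- isTRUE(all.equal(d_hub, d_core))
  label <- if (!tie && d_hub < d_core) "LHN" else "LKN"
  list(label = label, lambda_A = lambda_A, sqrt_kmax = sqrt_kmax,
       kappa_ratio = kappa, tie = tie)
}
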