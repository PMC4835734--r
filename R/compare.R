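#' Assemble the full comparison record for one network
#'
#' One row combining structure metrics, spectral summaries, the three
#' theoretical thresholds, the numerical threshold, per-method absolute and
#' relative errors, and the closest-method label. All components must refer
#' to the same (giant-component) graph. Records with an undefined DMP
#' threshold (trees) stay valid: the DMP error fields are \code{NA} and the
#' method is excluded from the closest-method competition.
#'
#' @param graph The analyzed graph (giant component).
#' @param name Network identifier.
#' @param lambda_c Numerical threshold from \code{\link{numerical_threshold}}.
#' @param thresholds Optional \code{\link{predict_thresholds}} result.
#' @param spectral_A,spectral_M Optional precomputed spectral summaries.
#' @param seed Seed for the modularity partition.
#' @return One-row \code{data.frame} (a "network record").
#' @export
build_record <- function(graph, name, lambda_c, thresholds = NULL,
                         spectral_A = NULL, spectral_M = NULL, seed = 1) {
  stopifnot(lambda_c > 0)
  if (is.null(spectral_A)) spectral_A <- adjacency_leading(graph)
  if (is.null(thresholds)) {
    thresholds <- predict_thresholds(graph, spectral_A, spectral_M)
  }
  if (is.null(spectral_M) && thresholds$dmp_defined) {
    spectral_M <- nb_leading(graph)
  }
  loc <- classify_localization(graph, spectral_A)
  sm <- structure_metrics(graph, name = name, seed = seed)

  preds <- c(MFL = thresholds$mfl, QMF = thresholds$qmf, DMP = thresholds$dmp)
  abs_err <- abs(preds - lambda_c)
  rel_err <- abs_err / lambda_c
  cm <- closest_method(abs_err)

  cbind(sm, data.frame(
    lambda_A = spectral_A$leading_eigenvalue,
    lambda_M = if (thresholds$dmp_defined) spectral_M$leading_eigenvalue else NA_real_,
    ipr_A = spectral_A$ipr,
    ipr_M = if (thresholds$dmp_defined) spectral_M$ipr else NA_real_,
    localization = loc$label,
    loc_tie = loc$tie,
    lc_mfl = thresholds$mfl,
    lc_qmf = thresholds$qmf,
    lc_dmp = thresholds$dmp,
    dmp_flag = thresholds$dmp_no_transition,
    lambda_c = as.numeric(lambda_c),
    abs_err_mfl = unname(abs_err["MFL"]),
    abs_err_qmf = unname(abs_err["QMF"]),
    abs_err_dmp = unname(abs_err["DMP"]),
    rel_err_mfl = unname(rel_err["MFL"]),
    rel_err_qmf = unname(rel_err["QMF"]),
    rel_err_dmp = unname(rel_err["DMP"]),
    closest_method = cm$method,
    closest_tie = cm$tie,
    stringsAsFactors = FALSE
  ))
}

# Closest predictor by absolute error among defined methods; ties (to
# floating-point resolution) broken lexicographically DMP < MFL < QMF and
# flagged.
closest_method <- function(abs_err) {
  ord <- c("DMP", "MFL", "QMF")
  e <- abs_err[ord]
  e <- e[!is.na(e)]
  if (length(e) == 0) return(list(method = NA_character_, tie = FALSE))
  best <- min(e)
  winners <- names(e)[e <= best + 1e-9 * max(1, best)]
  list(method = winners[1], tie = length(winners) > 1)
}

#' Relative frequency with which each method is closest
#'
#' Fraction of records in which each predictor comes closest (in absolute
#' error) to the numerical threshold; fractions sum to 1 over the competing
#' methods.
#'
#' @param records data.frame of rows from \code{\link{build_record}}.
#' @return Named numeric vector (MFL, QMF, DMP fractions).
#' @export
closest_frequency <- function(records) {
  ok <- !is.na(records$closest_method)
  if (!any(ok)) stop("no records with a defined closest method")
  tab <- table(factor(records$closest_method[ok],
                      levels = c("MFL", "QMF", "DMP")))
  stats::setNames(as.vector(tab) / sum(tab), names(tab))
}

#' Mean relative error binned by a structural covariate
#'
#' Per-method average relative error inside windows
#' \eqn{(x - \Delta x/2, x + \Delta x/2)} on a regular lattice of bin
#' centers at multiples of \eqn{\Delta x}, spanning the covariate range.
#' Empty bins are reported with \code{NA} means and a zero count, not as
#' zero error. Records with an undefined covariate are excluded and
#' counted.
#'
#' @param records data.frame of rows from \code{\link{build_record}}.
#' @param covariate One of \code{"r"}, \code{"c"}, \code{"Q"}.
#' @param delta_x Window width (default 0.1).
#' @return data.frame with \code{x} (bin centers), per-method mean relative
#'   errors, and \code{count}; attribute \code{"excluded"} gives the number
#'   of records dropped for an undefined covariate.
#' @export
binned_errors <- function(records, covariate = c("r", "c", "Q"),
                          delta_x = 0.1) {
  covariate <- match.arg(covariate)
  x <- records[[covariate]]
  keep <- !is.na(x)
  excluded <- sum(!keep)
  rec <- records[keep, , drop = FALSE]
  x <- x[keep]
  if (length(x) == 0) stop("no records with a defined covariate")
  centers <- seq(floor(min(x) / delta_x), ceiling(max(x) / delta_x)) * delta_x
  rows <- lapply(centers, function(ctr) {
    inbin <- x > ctr - delta_x / 2 & x <= ctr + delta_x / 2
    data.frame(
      x = ctr,
      rel_err_mfl = if (any(inbin)) mean(rec$rel_err_mfl[inbin], na.rm = TRUE) else NA_real_,
      rel_err_qmf = if (any(inbin)) mean(rec$rel_err_qmf[inbin], na.rm = TRUE) else NA_real_,
      rel_err_dmp = if (any(inbin)) mean(rec$rel_err_dmp[inbin], na.rm = TRUE) else NA_real_,
      count = sum(inbin)
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  attr(out, "covariate") <- covariate
  out
}

#' Threshold accuracy versus network size on configuration networks
#'
#' For each size N: generate an uncorrelated configuration network
#' (power-law degrees, minimum degree 3, structural cutoff), take its giant
#' component, compute the three theoretical thresholds and the numerical
#' chi-peak threshold, and tabulate absolute errors. This is the
#' size-scaling comparison of predictor accuracy.
#'
#' @param exponent Degree exponent \eqn{\nu_D > 2}.
#' @param sizes Increasing vector of node counts.
#' @param gamma Per-step recovery probability.
#' @param n_realizations Realizations per chi grid point.
#' @param master_seed Seed from which all per-stage seeds derive.
#' @param grid_points Points in the geometric lambda grid around the MFL
#'   threshold.
#' @param k_min Minimum degree.
#' @return data.frame with one row per size: N, lc_mfl, lc_qmf, lc_dmp,
#'   lambda_c, abs_err_mfl, abs_err_qmf, abs_err_dmp.
#' @export
size_scaling_experiment <- function(exponent, sizes, gamma = 1,
                                    n_realizations = 2000, master_seed = 1,
                                    grid_points = 25, k_min = 3) {
  stopifnot(all(diff(sizes) > 0), exponent > 2 || exponent > 1)
  rows <- lapply(seq_along(sizes), function(i) {
    n <- sizes[i]
    seed_i <- master_seed + 1000L * i
    g <- generate_configuration_network(n, exponent, k_min = k_min,
                                        seed = seed_i)
    g <- giant_component(g)
    th <- predict_thresholds(g)
    grid <- default_lambda_grid(th$mfl, points = grid_points, gamma = gamma)
    curve <- sweep_chi(g, grid, gamma = gamma,
                       n_realizations = n_realizations, seed = seed_i + 1L)
    lc <- suppressWarnings(numerical_threshold(curve))
    data.frame(N = n,
               lc_mfl = th$mfl, lc_qmf = th$qmf, lc_dmp = th$dmp,
               lambda_c = as.numeric(lc),
               abs_err_mfl = abs(th$mfl - lc),
               abs_err_qmf = abs(th$qmf - lc),
               abs_err_dmp = abs(th$dmp - lc))
  })
  do.call(rbind, rows)
}
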