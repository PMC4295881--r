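#' Empirical covariance (or correlation) of a block
#'
#' Blocks usually mix units (mmHg, percentages, expression levels), so the
#' default works on the correlation scale, i.e. on standardized variables;
#' covariance-scale fitting is available.
#'
#' @param block An [omics_block()] or numeric matrix (subjects x variables).
#' @param scale `"correlation"` (default) or `"covariance"`.
#' @return A list of class `cov_estimate` with `S`, `n`, `scale`,
#'   `variable_names`.
#' @export
cov_estimate <- function(block, scale = c("correlation", "covariance")) {
  scale <- match.arg(scale)
  x <- if (inherits(block, "omics_block")) block$data else as.matrix(block)
  S <- if (scale == "correlation") cor(x) else cov(x)
  structure(
    list(S = S, n = nrow(x), scale = scale,
         variable_names = colnames(x)),
    class = "cov_estimate"
  )
}

#' Sparse Gaussian graphical model by the graphical lasso
#'
#' Maximizes the l1-penalized Gaussian log-likelihood
#' `log det(Theta) - tr(S Theta) - lam * sum_{j != k} |Theta_jk|`
#' over positive-definite symmetric precision matrices (diagonal
#' unpenalized), by block coordinate descent. Edges of the conditional
#' independence graph are the nonzero off-diagonal entries; their weights are
#' the partial correlations `-Theta_jk / sqrt(Theta_jj Theta_kk)`.
#'
#' @param cov A [cov_estimate()] (or plain symmetric matrix).
#' @param lam Nonnegative l1 penalty.
#' @param tol Convergence tolerance on the working covariance (relative to
#'   the mean absolute off-diagonal of `S`). Default 1e-5.
#' @param maxit Outer-sweep cap. Default 500.
#' @param warm Optional previous fit used as warm start along a penalty path.
#' @return A list of class `ggm_fit` with `theta`, `lam`, `edge_count`,
#'   `partials`, `converged`, `iterations`.
#' @export
fit_sparse_ggm <- function(cov, lam, tol = 1e-5, maxit = 500L, warm = NULL) {
  S <- if (inherits(cov, "cov_estimate")) cov$S else as.matrix(cov)
  if (lam < 0) stop_invalid("lam must be >= 0")
  if (!isSymmetric(unname(S), tol = 1e-8)) stop_invalid("S must be symmetric")
  wW <- if (!is.null(warm)) warm$W else NULL
  wB <- if (!is.null(warm)) warm$B else NULL
  res <- glasso_cpp(unname(S), lam, tol, as.integer(maxit), wW, wB)
  if (!res$converged) {
    stop_invalid(sprintf(
      "graphical lasso did not converge in %d sweeps (residual gap %.3g)",
      maxit, res$delta
    ))
  }
  theta <- res$theta
  dimnames(theta) <- dimnames(S)
  partials <- precision_to_partial_corr(theta)
  edge_count <- sum(abs(theta[upper.tri(theta)]) > 1e-8)
  structure(
    list(theta = theta, lam = lam, edge_count = edge_count,
         partials = partials, converged = res$converged,
         iterations = res$iterations, W = res$W, B = res$B),
    class = "ggm_fit"
  )
}

#' Partial correlations from a precision matrix
#'
#' `rho_jk = -theta_jk / sqrt(theta_jj * theta_kk)`, diagonal set to 1. Note
#' the sign flip: a positive off-diagonal precision entry is a negative
#' partial correlation.
#'
#' @param theta Symmetric precision matrix with strictly positive diagonal.
#' @return The partial-correlation matrix.
#' @export
precision_to_partial_corr <- function(theta) {
  theta <- as.matrix(theta)
  if (!isSymmetric(unname(theta), tol = 1e-8)) stop_invalid("theta must be symmetric")
  d <- diag(theta)
  if (any(d <= 0)) stop_invalid("theta must have a strictly positive diagonal")
  rho <- -theta / sqrt(outer(d, d))
  diag(rho) <- 1
  rho
}

#' Calibrate the graphical-lasso penalty to an edge budget
#'
#' Bisects the penalty on a log-spaced bracket until the fitted edge count
#' matches `budget` (warm-starting each fit from its neighbour on the path).
#' If the exact count is not attainable -- the edge count is a step function
#' of the penalty -- the fit with the closest attainable count is returned,
#' preferring the larger penalty (sparser, more conservative) among equally
#' close candidates, and the deviation is reported.
#'
#' @param cov A [cov_estimate()].
#' @param budget Target number of edges, in `[0, p(p-1)/2]`.
#' @param max_steps Bisection step cap. Default 60.
#' @param tol,maxit Passed to [fit_sparse_ggm()].
#' @return A list with `lam`, `fit` (the selected `ggm_fit`), `budget`,
#'   `achieved`, `deviation`.
#' @export
calibrate_edge_budget <- function(cov, budget, max_steps = 60L,
                                  tol = 1e-5, maxit = 500L) {
  S <- if (inherits(cov, "cov_estimate")) cov$S else as.matrix(cov)
  p <- ncol(S)
  max_edges <- p * (p - 1) / 2
  if (budget < 0 || budget > max_edges) {
    stop_invalid("budget must be in [0, p(p-1)/2]")
  }
  off <- abs(S[upper.tri(S)])
  lam_max <- max(off) * 1.0001
  if (budget == 0) {
    fit <- fit_sparse_ggm(cov, lam_max, tol, maxit)
    return(list(lam = lam_max, fit = fit, budget = budget,
                achieved = fit$edge_count, deviation = fit$edge_count))
  }

  best <- NULL
  note_candidate <- function(lam, fit) {
    dev <- abs(fit$edge_count - budget)
    if (is.null(best) || dev < best$deviation ||
        (dev == best$deviation && lam > best$lam)) {
      best <<- list(lam = lam, fit = fit, budget = budget,
                    achieved = fit$edge_count, deviation = dev)
    }
  }

  # Walk the penalty down from the fully shrunk end with warm starts: the
  # solver stays in the sparse regime and never visits the (expensive) dense
  # end unless the budget demands it.
  lam_hi <- lam_max
  fit_hi <- fit_sparse_ggm(cov, lam_hi, tol, maxit)
  note_candidate(lam_hi, fit_hi)
  lam_lo <- lam_hi
  fit_lo <- fit_hi
  while (fit_lo$edge_count < budget) {
    if (lam_lo < lam_max * 1e-9) {
      stop_invalid(sprintf(
        "budget %d unreachable: at most %d edges attainable on this path",
        budget, fit_lo$edge_count
      ))
    }
    lam_hi <- lam_lo
    fit_hi <- fit_lo
    lam_lo <- lam_lo * 0.7
    fit_lo <- fit_sparse_ggm(cov, lam_lo, tol, maxit, warm = fit_hi)
    note_candidate(lam_lo, fit_lo)
  }

  warm <- fit_lo
  for (step in seq_len(max_steps)) {
    if (best$deviation == 0) break
    lam_mid <- sqrt(lam_lo * lam_hi)
    fit_mid <- fit_sparse_ggm(cov, lam_mid, tol, maxit, warm = warm)
    warm <- fit_mid
    note_candidate(lam_mid, fit_mid)
    if (fit_mid$edge_count > budget) lam_lo <- lam_mid else lam_hi <- lam_mid
    if (lam_hi / lam_lo < 1 + 1e-12) break
  }
  best
}

#' Intra-block partial-correlation network
#'
#' Fits the sparse Gaussian graphical model on one (preprocessed) block with
#' the penalty calibrated so the edge count equals `budget` -- by default the
#' block's node count, the density rule that keeps blocks of very different
#' sizes comparable after merging. Edge weights are partial correlations;
#' edges are tagged `ggm:<block>`.
#'
#' @param block An [omics_block()].
#' @param budget Edge budget; default `ncol(block$data)`.
#' @param scale Passed to [cov_estimate()].
#' @param ... Passed to [calibrate_edge_budget()].
#' @return An `igraph` network (see [new_network()]) with the calibration
#'   stored in graph attributes `lam`, `budget`, `achieved`.
#' @export
build_intra_network <- function(block, budget = NULL,
                                scale = c("correlation", "covariance"), ...) {
  stopifnot(inherits(block, "omics_block"))
  scale <- match.arg(scale)
  p <- ncol(block$data)
  if (is.null(budget)) budget <- p
  cov <- cov_estimate(block, scale = scale)
  cal <- calibrate_edge_budget(cov, budget, ...)
  theta <- cal$fit$theta
  sel <- which(upper.tri(theta) & abs(theta) > 1e-8, arr.ind = TRUE)
  vn <- block$variable_names
  edges <- data.frame(
    from = vn[sel[, 1]], to = vn[sel[, 2]],
    weight = cal$fit$partials[sel],
    estimator = sprintf("ggm:%s", block$block_label),
    stringsAsFactors = FALSE
  )
  nodes <- data.frame(name = vn, block = block$block_label,
                      stringsAsFactors = FALSE)
  g <- new_network(nodes, edges)
  igraph::graph_attr(g, "lam") <- cal$lam
  igraph::graph_attr(g, "budget") <- budget
  igraph::graph_attr(g, "achieved") <- cal$achieved
  g
}
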