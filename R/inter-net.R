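#' Ridge-regularized canonical correlation analysis
#'
#' Solves the CCA generalized eigenproblem with ridge terms added to each
#' block's covariance, `(S_xx + lam_x I)` and `(S_yy + lam_y I)`, so a
#' solution exists when variables outnumber subjects. Computation goes
#' through regularized whitening: the canonical correlations are the singular
#' values of `Cxx^{-1/2} S_xy Cyy^{-1/2}`, clipped to `[0, 1]`, and the
#' canonical weights are the back-transformed singular vectors. Successive
#' variates are uncorrelated under the regularized metric.
#'
#' @param X,Y [omics_block()]s (or matrices) on the same subjects.
#' @param lam_x,lam_y Nonnegative ridge weights. Zero requires the
#'   corresponding covariance to be nonsingular (`p < n`).
#' @param ncomp Number of canonical dimensions to retain (default 3).
#' @param scale Standardize variables first (default TRUE; blocks mix units).
#' @return A list of class `rcca_fit`: `can_corr`, `weights_x`, `weights_y`,
#'   `variates_x`, `variates_y`, `lam_x`, `lam_y`, `ncomp`.
#' @export
fit_rcca <- function(X, Y, lam_x = 0, lam_y = 0, ncomp = 3L, scale = TRUE) {
  xm <- if (inherits(X, "omics_block")) X$data else as.matrix(X)
  ym <- if (inherits(Y, "omics_block")) Y$data else as.matrix(Y)
  if (nrow(xm) != nrow(ym)) stop_invalid("X and Y must share subjects")
  if (lam_x < 0 || lam_y < 0) stop_invalid("ridge weights must be >= 0")
  px <- ncol(xm); py <- ncol(ym); n <- nrow(xm)
  if (ncomp > min(px, py)) stop_invalid("ncomp must be <= min(p_x, p_y)")

  xs <- base::scale(xm, center = TRUE, scale = scale)
  ys <- base::scale(ym, center = TRUE, scale = scale)
  Sxx <- crossprod(xs) / (n - 1)
  Syy <- crossprod(ys) / (n - 1)
  Sxy <- crossprod(xs, ys) / (n - 1)

  inv_sqrt <- function(C, lam, label) {
    Cr <- C
    diag(Cr) <- diag(Cr) + lam
    e <- eigen(Cr, symmetric = TRUE)
    if (min(e$values) < 1e-10) {
      stop_invalid(sprintf(
        "regularized covariance of %s is singular; use a positive ridge weight",
        label
      ))
    }
    e$vectors %*% (t(e$vectors) / sqrt(e$values))
  }
  Wx <- inv_sqrt(Sxx, lam_x, "X")
  Wy <- inv_sqrt(Syy, lam_y, "Y")
  K <- Wx %*% Sxy %*% Wy
  sv <- svd(K, nu = ncomp, nv = ncomp)
  d <- sv$d[seq_len(ncomp)]
  stopifnot(all(d < 1 + 1e-10)) # clipping must only absorb numerics
  can_corr <- pmin(pmax(d, 0), 1)

  wx <- Wx %*% sv$u
  wy <- Wy %*% sv$v
  rownames(wx) <- colnames(xm); rownames(wy) <- colnames(ym)
  structure(
    list(
      can_corr = can_corr,
      weights_x = wx, weights_y = wy,
      variates_x = xs %*% wx, variates_y = ys %*% wy,
      lam_x = lam_x, lam_y = lam_y, ncomp = as.integer(ncomp),
      scaled = scale
    ),
    class = "rcca_fit"
  )
}

#' Choose ridge weights by cross-validated first canonical correlation
#'
#' For every pair of grid values, M-fold cross-validation scores the ridge
#' pair by the mean held-out sample correlation between the projections onto
#' the first canonical pair; the maximizing pair is returned. Fold assignment
#' is seeded, so the selection is deterministic given the seed.
#'
#' @param X,Y Blocks on the same subjects.
#' @param grid Candidate ridge values (used for both blocks as a full cross
#'   product). Default `10^seq(-3, 0, length.out = 5)`.
#' @param folds Number of folds, >= 2. Default 5.
#' @param seed Integer seed for fold assignment.
#' @param scale Passed to [fit_rcca()].
#' @return A list with `lam_x`, `lam_y`, `score`, and the full `scores`
#'   matrix (rows: `lam_x` candidates; columns: `lam_y`).
#' @export
select_regularization <- function(X, Y, grid = 10^seq(-3, 0, length.out = 5),
                                  folds = 5L, seed = 1L, scale = TRUE) {
  xm <- if (inherits(X, "omics_block")) X$data else as.matrix(X)
  ym <- if (inherits(Y, "omics_block")) Y$data else as.matrix(Y)
  n <- nrow(xm)
  if (length(grid) < 1) stop_invalid("grid must be non-empty")
  if (folds < 2) stop_invalid("folds must be >= 2")
  if (n < folds) stop_invalid("more folds than subjects")
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))

  scores <- matrix(NA_real_, length(grid), length(grid),
                   dimnames = list(signif(grid, 3), signif(grid, 3)))
  for (a in seq_along(grid)) {
    for (b in seq_along(grid)) {
      fold_cor <- vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        fit <- fit_rcca(xm[tr, , drop = FALSE], ym[tr, , drop = FALSE],
                        lam_x = grid[a], lam_y = grid[b], ncomp = 1L,
                        scale = scale)
        mu_x <- colMeans(xm[tr, , drop = FALSE])
        mu_y <- colMeans(ym[tr, , drop = FALSE])
        sd_x <- apply(xm[tr, , drop = FALSE], 2, sd)
        sd_y <- apply(ym[tr, , drop = FALSE], 2, sd)
        xt <- sweep(sweep(xm[!tr, , drop = FALSE], 2, mu_x), 2,
                    if (scale) sd_x else rep(1, length(sd_x)), "/")
        yt <- sweep(sweep(ym[!tr, , drop = FALSE], 2, mu_y), 2,
                    if (scale) sd_y else rep(1, length(sd_y)), "/")
        u <- xt %*% fit$weights_x[, 1]
        v <- yt %*% fit$weights_y[, 1]
        if (sd(u) == 0 || sd(v) == 0) return(0)
        cor(u, v)
      }, numeric(1))
      scores[a, b] <- mean(fold_cor)
    }
  }
  best <- which(scores == max(scores), arr.ind = TRUE)[1, ]
  list(lam_x = grid[best[1]], lam_y = grid[best[2]],
       score = max(scores), scores = scores)
}

#' Cross-block relevance matrix from canonical variates
#'
#' Scores every cross-block variable pair through the canonical subspace:
#' with `Z_d = (variates_x[, d] + variates_y[, d]) / 2`, the score is
#' `M_jk = sum_d cor(x_j, Z_d) * cor(y_k, Z_d)` over the retained dimensions
#' -- the standard bipartite relevance-network construction for regularized
#' CCA. Entries are bounded by `ncomp` in absolute value.
#'
#' @param fit An [fit_rcca()] result fitted on these blocks.
#' @param X,Y The blocks the fit was computed on.
#' @return A numeric matrix (class `relevance_matrix`) of size `p_x` x `p_y`
#'   with attributes `ncomp`, `block_x`, `block_y`.
#' @export
relevance_matrix <- function(fit, X, Y) {
  stopifnot(inherits(fit, "rcca_fit"))
  xm <- if (inherits(X, "omics_block")) X$data else as.matrix(X)
  ym <- if (inherits(Y, "omics_block")) Y$data else as.matrix(Y)
  Z <- (fit$variates_x + fit$variates_y) / 2
  safe_cor <- function(mat, z) {
    sds <- apply(mat, 2, sd)
    out <- rep(0, ncol(mat))
    if (any(sds == 0)) {
      warning("zero-variance variable; its relevance scores set to 0",
              call. = FALSE)
    }
    ok <- sds > 0
    if (any(ok)) out[ok] <- cor(mat[, ok, drop = FALSE], z)
    out
  }
  M <- matrix(0, ncol(xm), ncol(ym),
              dimnames = list(colnames(xm), colnames(ym)))
  for (d in seq_len(fit$ncomp)) {
    if (sd(Z[, d]) == 0) next # degenerate dimension contributes nothing
    cx <- safe_cor(xm, Z[, d])
    cy <- safe_cor(ym, Z[, d])
    M <- M + outer(cx, cy)
  }
  structure(M, class = c("relevance_matrix", "matrix"),
            ncomp = fit$ncomp,
            block_x = if (inherits(X, "omics_block")) X$block_label else "x",
            block_y = if (inherits(Y, "omics_block")) Y$block_label else "y")
}

#' Bipartite cross-block network from a relevance matrix
#'
#' Keeps the `budget` largest entries of `|M|` -- by default the summed node
#' count of the two blocks, the pair-of-sets version of the density rule.
#' Ties at the cutoff are broken by lexicographic variable-name order so runs
#' are reproducible. Edges carry the signed relevance score and the tag
#' `cca:<blockX>-<blockY>`.
#'
#' @param M A [relevance_matrix()].
#' @param budget Number of edges to keep, `<= p_x * p_y`. Default
#'   `p_x + p_y`.
#' @return An `igraph` network over both blocks' variables.
#' @export
build_inter_network <- function(M, budget = NULL) {
  stopifnot(inherits(M, "relevance_matrix"))
  px <- nrow(M); py <- ncol(M)
  if (is.null(budget)) budget <- px + py
  if (budget > px * py) stop_invalid("budget must be <= p_x * p_y")
  bx <- attr(M, "block_x"); by <- attr(M, "block_y")
  pairs <- expand.grid(i = seq_len(px), j = seq_len(py))
  vx <- rownames(M)[pairs$i]
  vy <- colnames(M)[pairs$j]
  vals <- M[cbind(pairs$i, pairs$j)]
  ord <- order(-abs(vals), vx, vy)
  keep <- ord[seq_len(budget)]
  edges <- data.frame(
    from = vx[keep], to = vy[keep], weight = vals[keep],
    estimator = rep(sprintf("cca:%s-%s", bx, by), length(keep)),
    stringsAsFactors = FALSE
  )
  nodes <- data.frame(
    name = c(rownames(M), colnames(M)),
    block = c(rep(bx, px), rep(by, py)),
    stringsAsFactors = FALSE
  )
  new_network(nodes, edges)
}
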