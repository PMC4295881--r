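test_that("rCCA reduces to textbook CCA without regularization", {
  X <- omicfuse:::with_seed(1, matrix(rnorm(100 * 4), 100, 4))
  Y <- omicfuse:::with_seed(2, matrix(rnorm(100 * 3), 100, 3)) + 0.5 * X[, 1:3]
  fit <- fit_rcca(X, Y, 0, 0, ncomp = 3, scale = FALSE)
  oracle <- cancor(scale(X, scale = FALSE), scale(Y, scale = FALSE))
  expect_lt(max(abs(fit$can_corr - oracle$cor)), 1e-6)

  # identical blocks: first canonical correlation is 1
  self <- fit_rcca(X, X, 0, 0, ncomp = 2, scale = FALSE)
  expect_lt(abs(self$can_corr[1] - 1), 1e-8)

  # canonical correlations non-increasing and in [0, 1]
  expect_true(all(diff(fit$can_corr) <= 1e-12))
  expect_true(all(fit$can_corr >= 0 & fit$can_corr <= 1))
})

test_that("rCCA agrees with an independent ridge CCA implementation", {
  skip_if_not_installed("mixOmics")
  X <- omicfuse:::with_seed(11, matrix(rnorm(60 * 8), 60, 8))
  Y <- omicfuse:::with_seed(12, matrix(rnorm(60 * 6), 60, 6)) + 0.4 * X[, 1:6]
  fit <- fit_rcca(X, Y, 0.25, 0.4, ncomp = 3, scale = TRUE)
  ref <- mixOmics::rcc(scale(X), scale(Y), ncomp = 3,
                       lambda1 = 0.25, lambda2 = 0.4, method = "ridge")
  expect_lt(max(abs(fit$can_corr - ref$cor[1:3])), 0.02)
})

test_that("zero ridge on a singular block demands regularization", {
  X <- omicfuse:::with_seed(3, matrix(rnorm(10 * 20), 10, 20))
  Y <- omicfuse:::with_seed(4, matrix(rnorm(10 * 3), 10, 3))
  expect_error(fit_rcca(X, Y, 0, 0, ncomp = 2), "positive ridge")
  fit <- fit_rcca(X, Y, 0.5, 0.5, ncomp = 2)
  expect_true(all(fit$can_corr <= 1))
})

test_that("independent blocks yield a weak first canonical correlation", {
  X <- omicfuse:::with_seed(5, matrix(rnorm(2000 * 5), 2000, 5))
  Y <- omicfuse:::with_seed(6, matrix(rnorm(2000 * 4), 2000, 4))
  fit <- fit_rcca(X, Y, 0, 0, ncomp = 2)
  expect_lt(fit$can_corr[1], 0.25)
})

test_that("canonical correlations are invariant to variable permutation", {
  X <- omicfuse:::with_seed(7, matrix(rnorm(80 * 6), 80, 6))
  Y <- omicfuse:::with_seed(8, matrix(rnorm(80 * 5), 80, 5)) + 0.3 * X[, 1:5]
  f1 <- fit_rcca(X, Y, 0.1, 0.1, ncomp = 3)
  perm <- c(4, 1, 6, 2, 5, 3)
  f2 <- fit_rcca(X[, perm], Y, 0.1, 0.1, ncomp = 3)
  expect_lt(max(abs(f1$can_corr - f2$can_corr)), 1e-8)
})

test_that("successive variates are uncorrelated under the regularized metric", {
  X <- omicfuse:::with_seed(9, matrix(rnorm(100 * 6), 100, 6))
  Y <- omicfuse:::with_seed(10, matrix(rnorm(100 * 7), 100, 7))
  Y[, 1:6] <- Y[, 1:6] + 0.4 * X
  fit <- fit_rcca(X, Y, 0.2, 0.2, ncomp = 3)
  n <- nrow(X)
  Sxx <- crossprod(scale(X)) / (n - 1) + 0.2 * diag(6)
  gram <- t(fit$weights_x) %*% Sxx %*% fit$weights_x
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-6)
})

test_that("regularization selection is seeded and respects a singleton grid", {
  X <- omicfuse:::with_seed(13, matrix(rnorm(60 * 5), 60, 5))
  Y <- omicfuse:::with_seed(14, matrix(rnorm(60 * 4), 60, 4)) + 0.6 * X[, 1:4]
  single <- select_regularization(X, Y, grid = 0.3, folds = 3, seed = 1)
  expect_equal(single$lam_x, 0.3)
  expect_equal(single$lam_y, 0.3)

  s1 <- select_regularization(X, Y, grid = c(0.01, 0.1, 1), folds = 3, seed = 9)
  s2 <- select_regularization(X, Y, grid = c(0.01, 0.1, 1), folds = 3, seed = 9)
  expect_identical(s1, s2)
  expect_error(select_regularization(X, Y, folds = 100, seed = 1), "folds")
})

test_that("strongly coupled blocks get a high cross-validated score", {
  cfg <- simulation_config(n_subjects = 150, block_dims = c(10, 12),
                           block_names = c("x", "y"), n_latent = 2,
                           loading_scale = 1.5, loading_sparsity = 0.6,
                           seed = 31)
  s <- sample_multiblock(cfg)
  sel <- select_regularization(s$blocks$x, s$blocks$y,
                               grid = c(0.01, 0.1, 1), folds = 5, seed = 2)
  expect_gt(sel$score, 0.5)
  expect_true(is.finite(sel$lam_x) && is.finite(sel$lam_y))
})

test_that("relevance matrix scores planted pairs and respects symmetry", {
  # planted pair: the same signal duplicated across blocks
  z <- omicfuse:::with_seed(15, rnorm(200))
  X <- omicfuse:::with_seed(16, matrix(rnorm(200 * 5), 200, 5))
  Y <- omicfuse:::with_seed(17, matrix(rnorm(200 * 4), 200, 4))
  X[, 2] <- z + 0.1 * X[, 2]
  Y[, 3] <- z + 0.1 * Y[, 3]
  bx <- omics_block(X, "x"); by <- omics_block(Y, "y")
  fit <- fit_rcca(bx, by, 0.1, 0.1, ncomp = 1)
  M <- relevance_matrix(fit, bx, by)
  expect_equal(which.max(abs(M[2, ])), 3, ignore_attr = TRUE)
  expect_true(all(abs(M) <= attr(M, "ncomp") + 1e-12))

  # role symmetry: swapping blocks transposes M
  fit_sw <- fit_rcca(by, bx, 0.1, 0.1, ncomp = 1)
  M_sw <- relevance_matrix(fit_sw, by, bx)
  expect_lt(max(abs(unclass(M_sw) - t(unclass(M)))), 1e-8)

  # uncoupled blocks: all scores stay modest and far below a planted pair.
  # (The averaged-variate construction mixes within-block correlation into
  # Z even under the null, so null scores level off near 0.25-0.3 rather
  # than vanishing; the planted pair above scores ~0.9.)
  Xn <- omicfuse:::with_seed(18, matrix(rnorm(2000 * 15), 2000, 15))
  Yn <- omicfuse:::with_seed(19, matrix(rnorm(2000 * 12), 2000, 12))
  bn <- omics_block(Xn, "x"); bm <- omics_block(Yn, "y")
  fitn <- fit_rcca(bn, bm, 0.1, 0.1, ncomp = 2)
  Mn <- relevance_matrix(fitn, bn, bm)
  expect_lt(max(abs(Mn)), 0.35)
  expect_lt(max(abs(Mn)), abs(M[2, 3]) / 2)
})

test_that("inter network keeps the budgeted top scores with stable ties", {
  X <- omicfuse:::with_seed(20, matrix(rnorm(100 * 5), 100, 5))
  Y <- omicfuse:::with_seed(21, matrix(rnorm(100 * 4), 100, 4)) + 0.3 * X[, 1:4]
  bx <- omics_block(X, "x"); by <- omics_block(Y, "y")
  fit <- fit_rcca(bx, by, 0.1, 0.1, ncomp = 2)
  M <- relevance_matrix(fit, bx, by)

  g0 <- build_inter_network(M, budget = 0)
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 9)

  gfull <- build_inter_network(M, budget = 20)
  expect_equal(igraph::ecount(gfull), 20)

  g <- build_inter_network(M)
  expect_equal(igraph::ecount(g), 9)
  kept <- abs(igraph::E(g)$weight)
  expect_gte(min(kept), sort(abs(as.vector(unclass(M))), decreasing = TRUE)[9] - 1e-12)
  expect_true(all(startsWith(igraph::E(g)$estimator, "cca:x-y")))
})
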