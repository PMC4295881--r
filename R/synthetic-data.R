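#' Simulation settings for a synthetic multi-block cohort
#'
#' Bundles every knob of the cohort generator. The defaults emulate the
#' statistical shape of a longitudinal dietary-intervention study on obese
#' women: 135 subjects carrying three jointly measured variable blocks --
#' bio-clinical parameters (15 variables), adipose-tissue fatty-acid
#' percentages (30) and a targeted mRNA panel (221) -- with sparse
#' conditional-dependence structure inside each block and low-rank cross-block
#' coupling through shared latent factors.
#'
#' @param n_subjects Number of subjects (rows). Default 135.
#' @param block_dims Integer vector of block sizes. Default `c(15, 30, 221)`.
#' @param block_names Labels for the blocks, unique.
#' @param intra_density Fraction of possible off-diagonal precision entries
#'   that are nonzero, per block; recycled across blocks. Default 0.1.
#' @param n_latent Number of shared latent factors coupling the blocks.
#'   Default 3.
#' @param loading_scale Standard deviation of the nonzero factor loadings (in
#'   units of the per-variable noise scale, which is of order 1). `0` decouples
#'   the blocks. Default 0.5.
#' @param loading_sparsity Probability that a given variable loads on a given
#'   factor. Default 0.2.
#' @param group_probs Probabilities over the weight-change groups
#'   `c(WL, WS, WR)` (weight losers / stable / regainers); must sum to 1.
#'   Default is the observed stratification 45/135, 39/135, 51/135.
#' @param seed Integer seed; every stochastic draw of the generator flows from
#'   it.
#'
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 135L,
                              block_dims = c(15L, 30L, 221L),
                              block_names = c("bioclinical", "fatty_acid", "mrna"),
                              intra_density = 0.1,
                              n_latent = 3L,
                              loading_scale = 0.5,
                              loading_sparsity = 0.2,
                              group_probs = c(WL = 45, WS = 39, WR = 51) / 135,
                              seed = 1L) {
  if (n_subjects < 2) stop_invalid("n_subjects must be >= 2")
  if (any(block_dims < 2)) stop_invalid("all block_dims must be >= 2")
  if (length(block_names) != length(block_dims)) {
    stop_invalid("block_names and block_dims lengths differ")
  }
  if (anyDuplicated(block_names)) stop_invalid("block_names must be unique")
  intra_density <- rep_len(intra_density, length(block_dims))
  if (any(intra_density < 0 | intra_density > 1)) {
    stop_invalid("intra_density must be in [0, 1]")
  }
  if (abs(sum(group_probs) - 1) > 1e-8) stop_invalid("group_probs must sum to 1")
  if (length(group_probs) != 3L) stop_invalid("group_probs must have 3 entries (WL, WS, WR)")
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      block_dims = as.integer(block_dims),
      block_names = block_names,
      intra_density = intra_density,
      n_latent = as.integer(n_latent),
      loading_scale = loading_scale,
      loading_sparsity = loading_sparsity,
      group_probs = group_probs,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' A subject-by-variable data block
#'
#' The unit of intra-block network inference: one numeric matrix with subjects
#' in rows, plus a block label. Variable names must be unique; missing values
#' are not allowed.
#'
#' @param data Numeric matrix, subjects x variables, with dimnames.
#' @param block_label Single string naming the block.
#' @return A list of class `omics_block` with elements `data`,
#'   `variable_names`, `subject_ids`, `block_label`.
#' @export
omics_block <- function(data, block_label) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop_invalid("block data must be numeric")
  if (anyNA(data)) stop_invalid("block data must not contain missing values")
  if (is.null(colnames(data))) {
    colnames(data) <- sprintf("%s_%03d", block_label, seq_len(ncol(data)))
  }
  if (anyDuplicated(colnames(data))) stop_invalid("variable names must be unique")
  if (is.null(rownames(data))) {
    rownames(data) <- sprintf("S%03d", seq_len(nrow(data)))
  }
  structure(
    list(
      data = data,
      variable_names = colnames(data),
      subject_ids = rownames(data),
      block_label = as.character(block_label)
    ),
    class = "omics_block"
  )
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf(
    "<omics_block '%s'> %d subjects x %d variables\n",
    x$block_label, nrow(x$data), ncol(x$data)
  ))
  invisible(x)
}

#' Sparse symmetric positive-definite precision matrix
#'
#' Draws an off-diagonal support uniformly at the requested density with
#' random signs and magnitudes, then enforces positive definiteness by strict
#' diagonal dominance (each diagonal entry is set to the row's absolute
#' off-diagonal sum plus one). Diagonal dominance -- rather than squaring a
#' random factor -- keeps the declared support exact, which structure-recovery
#' tests rely on.
#'
#' @param p Dimension, >= 2.
#' @param density Fraction of the `p(p-1)/2` off-diagonal pairs that are
#'   nonzero, in `[0, 1]`. The realized count is `round(density * p(p-1)/2)`.
#' @param seed Integer seed.
#' @return A list with `theta` (the p x p precision matrix), `support`
#'   (two-column matrix of nonzero off-diagonal index pairs, i < j), `p`,
#'   `density`, `seed`.
#' @export
make_sparse_precision <- function(p, density, seed = 1L) {
  if (p < 2) stop_invalid("p must be >= 2")
  if (density < 0 || density > 1) stop_invalid("density must be in [0, 1]")
  n_pairs <- p * (p - 1L) / 2L
  n_edges <- round(density * n_pairs)
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  theta <- matrix(0, p, p)
  support <- matrix(integer(0), ncol = 2L,
                    dimnames = list(NULL, c("i", "j")))
  if (n_edges > 0) {
    sel <- with_seed(seed, {
      idx <- sample.int(n_pairs, n_edges)
      vals <- runif(n_edges, 0.5, 1) * sample(c(-1, 1), n_edges, replace = TRUE)
      list(idx = idx, vals = vals)
    })
    ij <- pairs[sel$idx, , drop = FALSE]
    theta[ij] <- sel$vals
    theta[ij[, c(2, 1), drop = FALSE]] <- sel$vals
    support <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
    colnames(support) <- c("i", "j")
  }
  diag(theta) <- rowSums(abs(theta)) + 1
  list(theta = theta, support = support, p = as.integer(p),
       density = density, seed = as.integer(seed))
}

#' Sample a multi-block Gaussian cohort with known ground truth
#'
#' Data for block b are `Z %*% t(L_b) + E_b`: `Z` holds `n_latent` standard
#' normal latent factors shared by all blocks, `L_b` is a sparse loading
#' matrix (cross-block coupling is therefore low rank, the structure that
#' regularized canonical correlation analysis is designed to detect), and
#' `E_b` is zero-mean Gaussian noise with covariance `solve(theta_b)` for a
#' sparse precision `theta_b` (the intra-block conditional-dependence
#' structure that the graphical lasso is asked to recover).
#'
#' @param config A [simulation_config()].
#' @return A list with `blocks` (list of [omics_block()]), `truth` (class
#'   `ground_truth`: per-block `precisions`, `loadings`, `true_intra_edges`,
#'   and `true_cross_pairs`, the cross-block pairs with nonzero induced
#'   marginal covariance), and `config`.
#' @export
sample_multiblock <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  n_blocks <- length(config$block_dims)
  seeds <- derive_seeds(config$seed, 2L * n_blocks + 1L)
  n <- config$n_subjects
  k <- config$n_latent

  Z <- with_seed(seeds[1L], matrix(rnorm(n * k), n, k))

  blocks <- vector("list", n_blocks)
  precisions <- loadings <- true_intra <- vector("list", n_blocks)
  names(blocks) <- names(precisions) <- names(loadings) <-
    names(true_intra) <- config$block_names

  for (b in seq_len(n_blocks)) {
    p <- config$block_dims[b]
    prec <- make_sparse_precision(p, config$intra_density[b], seeds[2L * b])
    sigma <- solve(prec$theta)
    Rchol <- chol(sigma)
    draws <- with_seed(seeds[2L * b + 1L], {
      list(
        E = matrix(rnorm(n * p), n, p),
        Lmask = matrix(runif(p * k) < config$loading_sparsity, p, k),
        Lval = matrix(rnorm(p * k, sd = max(config$loading_scale, 0)), p, k)
      )
    })
    L <- draws$Lval * draws$Lmask
    if (config$loading_scale == 0) L[] <- 0
    X <- Z %*% t(L) + draws$E %*% Rchol
    vname <- sprintf("%s_%03d", config$block_names[b], seq_len(p))
    dimnames(X) <- list(sprintf("S%03d", seq_len(n)), vname)
    blocks[[b]] <- omics_block(X, config$block_names[b])
    precisions[[b]] <- prec$theta
    loadings[[b]] <- L
    sup <- prec$support
    true_intra[[b]] <- data.frame(
      var_i = vname[sup[, 1]], var_j = vname[sup[, 2]],
      stringsAsFactors = FALSE
    )
  }

  cross <- list()
  for (a in seq_len(n_blocks - 1L)) {
    for (b in seq((a + 1L), n_blocks)) {
      cc <- loadings[[a]] %*% t(loadings[[b]])
      nz <- which(abs(cc) > 1e-12, arr.ind = TRUE)
      if (nrow(nz)) {
        cross[[length(cross) + 1L]] <- data.frame(
          block_x = config$block_names[a],
          var_x = blocks[[a]]$variable_names[nz[, 1]],
          block_y = config$block_names[b],
          var_y = blocks[[b]]$variable_names[nz[, 2]],
          coupling = cc[nz],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  cross <- if (length(cross)) do.call(rbind, cross) else
    data.frame(block_x = character(0), var_x = character(0),
               block_y = character(0), var_y = character(0),
               coupling = numeric(0), stringsAsFactors = FALSE)

  truth <- structure(
    list(precisions = precisions, loadings = loadings,
         true_intra_edges = true_intra, true_cross_pairs = cross),
    class = "ground_truth"
  )
  list(blocks = blocks, truth = truth, config = config)
}

#' Simulate body-weight trajectories over a two-phase dietary intervention
#'
#' Each subject gets a baseline weight, a weight after a low calorie diet
#' (LCD; an 8-13% loss, matching the >= 8% inclusion rule of the emulated
#' trial) and a weight after the weight maintenance phase (WMD). The WMD
#' change is drawn from a group-specific range so the +/- 2 kg classifier
#' recovers the drawn labels exactly: weight losers (WL) change by
#' `-2 - |N(5, 2.5)|` kg, regainers (WR) by `+2 + |N(3, 2)|` kg, stable (WS)
#' uniformly inside the open interval (-2, 2).
#'
#' @param n Number of subjects.
#' @param group_probs Probabilities over `c(WL, WS, WR)`, summing to 1.
#' @param seed Integer seed.
#' @return A data.frame (the cohort table) with `subject_id`, `weight_bas`,
#'   `weight_lcd`, `weight_wmd` (kg) and `group_label`.
#' @export
simulate_weight_trajectories <- function(n,
                                         group_probs = c(WL = 45, WS = 39, WR = 51) / 135,
                                         seed = 1L) {
  if (abs(sum(group_probs) - 1) > 1e-8) stop_invalid("group_probs must sum to 1")
  if (length(group_probs) != 3L) stop_invalid("group_probs must have 3 entries")
  with_seed(seed, {
    grp <- sample(c("WL", "WS", "WR"), n, replace = TRUE, prob = group_probs)
    bas <- pmin(pmax(rnorm(n, mean = 94, sd = 15), 66), 150)
    lcd <- bas * (1 - runif(n, 0.08, 0.13))
    delta <- numeric(n)
    delta[grp == "WL"] <- -2 - abs(rnorm(sum(grp == "WL"), 5, 2.5))
    delta[grp == "WR"] <- 2 + abs(rnorm(sum(grp == "WR"), 3, 2))
    delta[grp == "WS"] <- runif(sum(grp == "WS"), -2, 2)
    wmd <- lcd + delta
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      weight_bas = bas, weight_lcd = lcd, weight_wmd = wmd,
      group_label = factor(grp, levels = c("WL", "WS", "WR")),
      stringsAsFactors = FALSE
    )
  })
}

#' Write / read ground truth as JSON
#'
#' Dense matrices are stored as nested arrays at full double precision, so the
#' round trip is lossless.
#'
#' @param truth A `ground_truth` object.
#' @param path File path.
#' @return `write_ground_truth` returns `path` invisibly; `read_ground_truth`
#'   returns the `ground_truth` object.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- list(
    precisions = lapply(truth$precisions, unname),
    loadings = lapply(truth$loadings, unname),
    true_intra_edges = truth$true_intra_edges,
    true_cross_pairs = truth$true_cross_pairs
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(x) {
    if (is.list(x)) do.call(rbind, x) else as.matrix(x)
  }
  fix_df <- function(d, cols) {
    if (is.data.frame(d) && nrow(d) > 0) return(d)
    stats::setNames(
      as.data.frame(rep(list(character(0)), length(cols))), cols
    )
  }
  structure(
    list(
      precisions = lapply(raw$precisions, as_mat),
      loadings = lapply(raw$loadings, as_mat),
      true_intra_edges = lapply(raw$true_intra_edges, fix_df,
                                cols = c("var_i", "var_j")),
      true_cross_pairs = fix_df(raw$true_cross_pairs,
                                cols = c("block_x", "var_x", "block_y",
                                         "var_y", "coupling"))
    ),
    class = "ground_truth"
  )
}

#' Write a block or cohort table as delimited text
#'
#' Blocks are written subjects-in-rows with a header row of variable names and
#' a leading `subject_id` column.
#'
#' @param block An [omics_block()].
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_block <- function(block, path, sep = "\t") {
  stopifnot(inherits(block, "omics_block"))
  df <- data.frame(subject_id = block$subject_ids, block$data,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
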