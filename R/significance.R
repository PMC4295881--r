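#' Degree-preserving rewiring (configuration-model null)
#'
#' Randomizes a graph by `swap_factor * |E|` attempted double-edge swaps
#' (replacing `{a,b},{c,d}` with `{a,c},{b,d}`), rejecting any swap that
#' would create a self-loop or parallel edge, via
#' [igraph::rewire()]`(keeping_degseq(...))`. Every node's degree is exactly
#' preserved. Edge attributes are dropped: null graphs are structural.
#' Graphs with fewer than two edges (no feasible swap) are returned as an
#' isomorphic copy.
#'
#' @param g A network.
#' @param swap_factor Attempted swaps per edge. Default 10.
#' @param seed Integer seed.
#' @return The rewired `igraph` (vertex names and blocks kept).
#' @export
rewire_preserving_degrees <- function(g, swap_factor = 10L, seed = 1L) {
  m <- igraph::ecount(g)
  if (m < 2) {
    out <- g
  } else {
    out <- with_seed(seed, igraph::rewire(
      g, igraph::keeping_degseq(loops = FALSE, niter = swap_factor * m)
    ))
  }
  for (a in igraph::edge_attr_names(out)) {
    out <- igraph::delete_edge_attr(out, a)
  }
  out
}

#' Permutation test for the significance of the modularity
#'
#' Clusters `B` degree-preserving rewirings of the graph with the same
#' spin-glass annealer (fresh sub-seed per replicate; anything less would
#' bias the null downward) and compares the observed modularity with the
#' null maxima. The clustering is declared significant if the observed
#' modularity exceeds the maximum modularity over the `B` random graphs; an
#' add-one permutation p-value `(1 + #{null >= obs}) / (B + 1)` is also
#' reported, never below `1/(B+1)`.
#'
#' @param g A network with at least one edge.
#' @param B Number of null replicates. Default 100.
#' @param seed Integer seed.
#' @param swap_factor Passed to [rewire_preserving_degrees()].
#' @param ... Passed to [spinglass_cluster()] (spins, schedule, ...).
#' @return A list with `significant`, `observed_q`, `p_value`, `partition`
#'   (the observed [spinglass_cluster()] result) and `null` (a
#'   `null_ensemble`: statistic name, `B`, `null_values`, `seed`,
#'   `swap_factor`).
#' @export
modularity_significance <- function(g, B = 100L, seed = 1L,
                                    swap_factor = 10L, ...) {
  seeds <- derive_seeds(seed, 2L * max(B, 1L) + 1L)
  part <- spinglass_cluster(g, seed = seeds[1L], ...)
  null_q <- numeric(B)
  for (b in seq_len(B)) {
    gb <- rewire_preserving_degrees(g, swap_factor, seed = seeds[2L * b])
    null_q[b] <- spinglass_cluster(gb, seed = seeds[2L * b + 1L], ...)$q
  }
  ens <- structure(
    list(statistic = "modularity", B = as.integer(B), null_values = null_q,
         seed = as.integer(seed), swap_factor = as.integer(swap_factor)),
    class = "null_ensemble"
  )
  significant <- B > 0 && part$q > max(null_q)
  p <- (1 + sum(null_q >= part$q)) / (B + 1)
  list(significant = significant, observed_q = part$q, p_value = p,
       partition = part, null = ens)
}

#' Permutation test for within-cluster betweenness
#'
#' Computes shortest-path betweenness (unweighted; endpoints excluded) on a
#' cluster's induced subgraph and tests each node against a degree-preserving
#' null: by default each replicate contributes its *maximum* betweenness, and
#' a node's p-value is `(1 + #{replicate maxima >= observed}) / (B + 1)` --
#' so significance means a betweenness in the top tail of what any node
#' achieves on graphs with this exact degree sequence, i.e. more central than
#' the node's degree forces. A pooled per-node null is available as an
#' option. Subgraphs with fewer than 3 nodes have zero betweenness and p = 1.
#'
#' @param g The induced subgraph of one cluster.
#' @param B Number of null replicates. Default 100.
#' @param seed Integer seed.
#' @param swap_factor Passed to [rewire_preserving_degrees()].
#' @param null `"max"` (default) or `"pooled"`.
#' @param alpha Significance level. Default 0.05.
#' @return A data.frame (the betweenness report): `node`, `degree`,
#'   `betweenness`, `p_value`, `significant`, `is_hub` (maximal degree in
#'   the subgraph). The null values are attached as attribute
#'   `null_ensemble`.
#' @export
betweenness_significance <- function(g, B = 100L, seed = 1L,
                                     swap_factor = 10L,
                                     null = c("max", "pooled"),
                                     alpha = 0.05) {
  null <- match.arg(null)
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  obs <- if (n >= 3) igraph::betweenness(g, weights = NA) else rep(0, n)
  if (n < 3 || igraph::ecount(g) < 2 || B == 0) {
    return(report_bw(g, deg, obs, rep(1, n), alpha, numeric(0), B, seed,
                     swap_factor))
  }
  seeds <- derive_seeds(seed, B)
  null_vals <- if (null == "max") numeric(B) else
    vector("list", B)
  for (b in seq_len(B)) {
    gb <- rewire_preserving_degrees(g, swap_factor, seed = seeds[b])
    bw <- igraph::betweenness(gb, weights = NA)
    if (null == "max") null_vals[b] <- max(bw) else null_vals[[b]] <- bw
  }
  if (null == "max") {
    p <- vapply(obs, function(o) (1 + sum(null_vals >= o)) / (B + 1),
                numeric(1))
    ens_values <- null_vals
  } else {
    pool <- unlist(null_vals)
    p <- vapply(obs, function(o) (1 + sum(pool >= o)) / (length(pool) + 1),
                numeric(1))
    ens_values <- pool
  }
  report_bw(g, deg, obs, p, alpha, ens_values, B, seed, swap_factor)
}

report_bw <- function(g, deg, obs, p, alpha, null_values, B, seed,
                      swap_factor) {
  rep <- data.frame(
    node = igraph::V(g)$name %||% as.character(seq_along(deg)),
    degree = as.integer(deg),
    betweenness = obs,
    p_value = p,
    significant = p < alpha,
    is_hub = deg == max(deg),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(rep, "null_ensemble") <- structure(
    list(statistic = "max_betweenness", B = as.integer(B),
         null_values = null_values, seed = as.integer(seed),
         swap_factor = as.integer(swap_factor)),
    class = "null_ensemble"
  )
  rep
}

#' Extract hubs per cluster
#'
#' For each cluster, returns the `k` nodes with the largest degree measured
#' on the full network, including all ties at rank `k`.
#'
#' @param g The (global) network.
#' @param assignment Cluster ids (vertex order or named by node).
#' @param k Number of top-degree ranks per cluster. Default 1.
#' @return A named list: per cluster, a character vector of hub node names.
#' @export
extract_hubs <- function(g, assignment, k = 1L) {
  member <- align_assignment(g, assignment)
  deg <- igraph::degree(g)
  vn <- igraph::V(g)$name
  out <- lapply(split(seq_along(member), member), function(idx) {
    d <- deg[idx]
    cutoff <- sort(d, decreasing = TRUE)[min(k, length(d))]
    vn[idx][d >= cutoff]
  })
  names(out) <- paste0("cluster_", names(out))
  out
}

#' Serialize a permutation null ensemble as JSON
#'
#' @param ensemble A `null_ensemble` (from [modularity_significance()] or
#'   [betweenness_significance()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_null_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  jsonlite::write_json(unclass(ensemble), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}
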