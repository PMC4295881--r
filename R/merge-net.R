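#' Construct a typed, signed, weighted undirected network
#'
#' The common graph container of the package: a simple undirected `igraph`
#' whose vertices carry a `block` label and whose edges carry `weight`
#' (signed association strength), `sign` (+1/-1, redundant with the weight's
#' sign but convenient for viewers) and `estimator` (the family that produced
#' the edge, e.g. `"ggm:mrna"` or `"cca:bioclinical-mrna"`). Weights are only
#' comparable within one estimator family; no function in the package ranks
#' weights across families.
#'
#' @param nodes data.frame with columns `name`, `block`.
#' @param edges data.frame with columns `from`, `to`, `weight`, `estimator`.
#' @return An `igraph` object.
#' @export
new_network <- function(nodes, edges) {
  stopifnot(all(c("name", "block") %in% names(nodes)))
  if (anyDuplicated(nodes$name)) stop_invalid("node names must be unique")
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to", "weight", "estimator") %in% names(edges)))
    missing <- setdiff(c(edges$from, edges$to), nodes$name)
    if (length(missing)) {
      stop_invalid("edge endpoints not in node set: ",
                   paste(missing, collapse = ", "))
    }
    if (any(edges$from == edges$to)) stop_invalid("self-loops are not allowed")
    key <- pair_key(edges$from, edges$to)
    if (anyDuplicated(key)) {
      stop_invalid("parallel edges: ", key[duplicated(key)][1])
    }
    edges$sign <- ifelse(edges$weight >= 0, 1L, -1L)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), estimator = character(0),
                        sign = integer(0), stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

# canonical unordered-pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Merge intra- and inter-block networks into one global network
#'
#' Takes the union of nodes and edges of the source networks (three
#' intra-block partial-correlation networks and three cross-block relevance
#' networks in the standard pipeline). Estimator families partition the space
#' of variable pairs -- an intra pair can only come from its block's GGM, a
#' cross pair only from that pair's CCA -- so an identical unordered pair
#' arriving from two sources indicates corrupted input and raises an
#' integrity error naming the pair.
#'
#' @param sources List of networks from [new_network()] (any order; the merge
#'   is order-invariant).
#' @return The global `igraph` network, with a `provenance` graph attribute
#'   listing each source's estimator tags and edge count.
#' @export
merge_networks <- function(sources) {
  stopifnot(is.list(sources), length(sources) >= 1)
  node_list <- lapply(sources, function(g) {
    data.frame(name = igraph::V(g)$name, block = igraph::V(g)$block,
               stringsAsFactors = FALSE)
  })
  nodes <- unique(do.call(rbind, node_list))
  if (anyDuplicated(nodes$name)) {
    stop_invalid("a node name appears with two different block labels")
  }
  nodes <- nodes[order(nodes$name), , drop = FALSE]

  edge_list <- lapply(sources, function(g) {
    igraph::as_data_frame(g, what = "edges")
  })
  edges <- do.call(rbind, edge_list)
  if (nrow(edges) > 0) {
    key <- pair_key(edges$from, edges$to)
    if (anyDuplicated(key)) {
      stop_invalid("duplicate edge across sources: ",
                   key[duplicated(key)][1])
    }
    edges <- edges[order(pair_key(edges$from, edges$to)), , drop = FALSE]
  }
  g <- new_network(nodes, edges)
  igraph::graph_attr(g, "provenance") <- lapply(sources, function(s) {
    list(estimators = unique(igraph::E(s)$estimator),
         edges = igraph::ecount(s),
         budget = igraph::graph_attr(s, "budget") %||% NA)
  })
  g
}

#' Per-node degrees and per-block edge densities
#'
#' Degree is the number of adjacent edges in the (global) network. Block
#' density is the number of within-block edges divided by the number of
#' possible pairs `p_b (p_b - 1) / 2`; under the node-count edge budget the
#' largest blocks get the smallest densities.
#'
#' @param g A network from [new_network()] / [merge_networks()].
#' @return A list with `nodes` (data.frame: `name`, `block`, `degree`) and
#'   `block_density` (data.frame: `block`, `p`, `edges_within`, `density`).
#' @export
degree_table <- function(g) {
  nodes <- data.frame(
    name = igraph::V(g)$name,
    block = igraph::V(g)$block,
    degree = igraph::degree(g),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ed <- igraph::as_data_frame(g, what = "edges")
  blk <- stats::setNames(nodes$block, nodes$name)
  dens <- do.call(rbind, lapply(unique(nodes$block), function(b) {
    p <- sum(nodes$block == b)
    within <- if (nrow(ed)) sum(blk[ed$from] == b & blk[ed$to] == b) else 0L
    data.frame(block = b, p = p, edges_within = within,
               density = if (p > 1) within / (p * (p - 1) / 2) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(nodes = nodes, block_density = dens)
}
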