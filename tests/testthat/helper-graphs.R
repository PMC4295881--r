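# Graph fixtures built in code.

# k disjoint cliques of size s, optionally closed into a ring by single
# bridge edges between consecutive cliques.
make_cliques <- function(k, s, ring = FALSE) {
  nodes <- sprintf("n%02d", seq_len(k * s))
  edges <- do.call(rbind, lapply(seq_len(k), function(ci) {
    ix <- ((ci - 1) * s + 1):(ci * s)
    cmb <- t(combn(nodes[ix], 2))
    data.frame(from = cmb[, 1], to = cmb[, 2], weight = 1,
               estimator = "ggm:test", stringsAsFactors = FALSE)
  }))
  if (ring && k > 1) {
    bridges <- do.call(rbind, lapply(seq_len(k), function(ci) {
      a <- nodes[(ci - 1) * s + 1]
      b <- nodes[(ci %% k) * s + 2]
      data.frame(from = a, to = b, weight = 1, estimator = "ggm:test",
                 stringsAsFactors = FALSE)
    }))
    edges <- rbind(edges, bridges)
  }
  new_network(data.frame(name = nodes, block = "test",
                         stringsAsFactors = FALSE), edges)
}

# Barbell: two s-cliques joined through a 2-node bridge path.
make_barbell <- function(s = 5) {
  nodes <- c(sprintf("a%02d", seq_len(s)), "b1", "b2",
             sprintf("c%02d", seq_len(s)))
  clique_edges <- function(vs) {
    cmb <- t(combn(vs, 2))
    data.frame(from = cmb[, 1], to = cmb[, 2], weight = 1,
               estimator = "ggm:test", stringsAsFactors = FALSE)
  }
  edges <- rbind(
    clique_edges(nodes[seq_len(s)]),
    clique_edges(nodes[(s + 3):(2 * s + 2)]),
    data.frame(from = c(nodes[1], "b1", "b2"),
               to = c("b1", "b2", nodes[s + 3]),
               weight = 1, estimator = "ggm:test", stringsAsFactors = FALSE)
  )
  new_network(data.frame(name = nodes, block = "test",
                         stringsAsFactors = FALSE), edges)
}

# Erdos-Renyi G(n, p) as an omicfuse network (seeded).
make_er <- function(n, p, seed) {
  nodes <- sprintf("v%03d", seq_len(n))
  cmb <- t(combn(nodes, 2))
  keep <- omicfuse:::with_seed(seed, runif(nrow(cmb)) < p)
  edges <- data.frame(from = cmb[keep, 1], to = cmb[keep, 2], weight = 1,
                      estimator = "ggm:test", stringsAsFactors = FALSE)
  new_network(data.frame(name = nodes, block = "test",
                         stringsAsFactors = FALSE), edges)
}

# Small synthetic block sampled from a known sparse precision.
make_ggm_block <- function(p = 20, density = 0.1, n = 500, seed = 1,
                           label = "test") {
  pr <- make_sparse_precision(p, density, seed)
  R <- chol(solve(pr$theta))
  X <- omicfuse:::with_seed(seed + 1000, matrix(rnorm(n * p), n, p)) %*% R
  colnames(X) <- sprintf("%s_%03d", label, seq_len(p))
  list(block = omics_block(X, label), precision = pr)
}
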