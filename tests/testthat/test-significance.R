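test_that("rewiring preserves degrees and yields simple graphs", {
  g <- make_er(20, 0.25, seed = 2)
  for (seed in 1:5) {
    r <- rewire_preserving_degrees(g, swap_factor = 10, seed = seed)
    expect_equal(igraph::degree(r)[igraph::V(g)$name],
                 igraph::degree(g)[igraph::V(g)$name])
    expect_equal(igraph::ecount(r), igraph::ecount(g))
    expect_true(igraph::is_simple(r))
    expect_equal(igraph::edge_attr_names(r), character(0))
  }
  # deterministic given seed
  r1 <- rewire_preserving_degrees(g, seed = 42)
  r2 <- rewire_preserving_degrees(g, seed = 42)
  expect_identical(igraph::as_edgelist(r1), igraph::as_edgelist(r2))
})

test_that("uniquely realizable degree sequences rewire to themselves", {
  # path a-b-c: only one simple graph on degrees (1, 2, 1)
  path <- new_network(
    data.frame(name = c("a", "b", "c"), block = "x"),
    data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1,
               estimator = "ggm:x")
  )
  r <- rewire_preserving_degrees(path, seed = 1)
  expect_equal(unname(sort(igraph::degree(r))), c(1, 1, 2))
  expect_equal(unname(igraph::degree(r)["b"]), 2)

  # star on 6 nodes: unique realization up to leaf labels
  star <- new_network(
    data.frame(name = c("hub", paste0("l", 1:5)), block = "x"),
    data.frame(from = "hub", to = paste0("l", 1:5), weight = 1,
               estimator = "ggm:x")
  )
  r2 <- rewire_preserving_degrees(star, seed = 3)
  expect_equal(unname(igraph::degree(r2)["hub"]), 5)
  expect_equal(igraph::ecount(r2), 5)
})

test_that("modularity permutation test flags planted structure only", {
  # strong planted structure: two 8-cliques with one bridge
  g <- make_cliques(2, 8)
  g <- igraph::add_edges(g, c("n01", "n09"))
  igraph::E(g)$weight[igraph::ecount(g)] <- 1
  igraph::E(g)$estimator[igraph::ecount(g)] <- "ggm:test"
  res <- modularity_significance(g, B = 100, seed = 1)
  expect_true(res$significant)
  expect_equal(res$null$B, 100L)
  expect_length(res$null$null_values, 100)
  expect_gte(res$p_value, 1 / 101)

  # determinism
  res2 <- modularity_significance(g, B = 20, seed = 5)
  res3 <- modularity_significance(g, B = 20, seed = 5)
  expect_identical(res2$null$null_values, res3$null$null_values)
  expect_identical(res2$p_value, res3$p_value)

  # vacuous null: B = 0 cannot be significant
  res0 <- modularity_significance(g, B = 0, seed = 1)
  expect_false(res0$significant)
})

test_that("modularity test is calibrated on unstructured graphs", {
  hits <- 0
  for (seed in 1:10) {
    g <- make_er(40, 0.3, seed = seed + 400)
    res <- modularity_significance(g, B = 100, seed = seed)
    hits <- hits + res$significant
  }
  expect_lte(hits, 2)
})

test_that("betweenness significance handles forced and unforced centrality", {
  # path: the middle node is exactly as central as its degree forces
  path <- new_network(
    data.frame(name = c("a", "b", "c"), block = "x"),
    data.frame(from = c("a", "b"), to = c("b", "c"), weight = 1,
               estimator = "ggm:x")
  )
  rep <- betweenness_significance(path, B = 50, seed = 1)
  expect_equal(rep$betweenness[rep$node == "b"], 1)
  expect_equal(rep$p_value[rep$node == "b"], 1)
  expect_false(any(rep$significant))

  # star center: maximal betweenness, still forced by degree; is_hub set
  star <- new_network(
    data.frame(name = c("hub", paste0("l", 1:5)), block = "x"),
    data.frame(from = "hub", to = paste0("l", 1:5), weight = 1,
               estimator = "ggm:x")
  )
  rep2 <- betweenness_significance(star, B = 50, seed = 2)
  hubrow <- rep2[rep2$node == "hub", ]
  expect_equal(hubrow$p_value, 1)
  expect_true(hubrow$is_hub)
  expect_false(hubrow$significant)

  # tiny subgraphs: all zero, p = 1
  pair <- new_network(
    data.frame(name = c("a", "b"), block = "x"),
    data.frame(from = "a", to = "b", weight = 1, estimator = "ggm:x")
  )
  rep3 <- betweenness_significance(pair, B = 50, seed = 3)
  expect_true(all(rep3$betweenness == 0))
  expect_true(all(rep3$p_value == 1))
})

test_that("barbell bridge nodes are betweenness-significant", {
  g <- make_barbell(5)
  hits <- 0
  for (seed in 1:10) {
    rep <- betweenness_significance(g, B = 100, seed = seed)
    bridge <- rep[rep$node %in% c("b1", "b2"), ]
    hits <- hits + all(bridge$significant)
  }
  expect_gte(hits, 9)
})

test_that("permutation p-values are bounded below by 1/(B+1)", {
  g <- make_barbell(4)
  for (B in c(10, 50)) {
    rep <- betweenness_significance(g, B = B, seed = 1)
    expect_true(all(rep$p_value >= 1 / (B + 1)))
    expect_true(all(rep$p_value <= 1))
  }
  res <- modularity_significance(make_cliques(2, 5), B = 20, seed = 1)
  expect_gte(res$p_value, 1 / 21)
})

test_that("pooled null option gives valid, generally smaller p-values", {
  g <- make_barbell(5)
  rep_max <- betweenness_significance(g, B = 50, seed = 4, null = "max")
  rep_pool <- betweenness_significance(g, B = 50, seed = 4, null = "pooled")
  expect_true(all(rep_pool$p_value > 0 & rep_pool$p_value <= 1))
  bridge <- rep_pool$node %in% c("b1", "b2")
  expect_true(all(rep_pool$p_value[bridge] <= rep_max$p_value[bridge]))
})

test_that("hub extraction returns top-degree nodes with ties included", {
  g <- make_barbell(5)
  part <- stats::setNames(rep(1, igraph::vcount(g)), igraph::V(g)$name)
  hubs <- extract_hubs(g, part)
  # clique members adjacent to the bridge have degree 5; both are tied
  deg <- igraph::degree(g)
  expect_setequal(hubs$cluster_1, names(deg)[deg == max(deg)])

  # a clique cluster: everyone tied at k = 1
  cl <- make_cliques(1, 4)
  hubs2 <- extract_hubs(cl, stats::setNames(rep(1, 4), igraph::V(cl)$name))
  expect_length(hubs2$cluster_1, 4)

  # star: center only
  star <- new_network(
    data.frame(name = c("hub", paste0("l", 1:4)), block = "x"),
    data.frame(from = "hub", to = paste0("l", 1:4), weight = 1,
               estimator = "ggm:x")
  )
  hubs3 <- extract_hubs(star, stats::setNames(rep(1, 5), igraph::V(star)$name))
  expect_equal(hubs3$cluster_1, "hub")
})
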