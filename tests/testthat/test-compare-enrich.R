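test_that("overlap test matches the hypergeometric tail and fisher.test", {
  universe <- sprintf("g%02d", 1:40)
  a <- universe[1:10]
  b <- universe[1:10]
  ot <- overlap_test(a, b, universe)
  expect_equal(ot$overlap, 10)
  # closed-form tail: all of a drawn inside b
  expect_equal(ot$p_value, 1 / choose(40, 10), tolerance = 1e-12)

  # agreement with the one-sided Fisher exact test on the 2x2 table
  b2 <- universe[6:20]
  ot2 <- overlap_test(a, b2, universe)
  ft <- fisher.test(matrix(c(ot2$table["both"], ot2$table["a_only"],
                             ot2$table["b_only"], ot2$table["neither"]),
                           2, 2), alternative = "greater")
  expect_equal(ot2$p_value, ft$p.value, tolerance = 1e-10)
  expect_equal(sum(ot2$table), 40)

  # saturated and empty overlaps
  expect_equal(overlap_test(universe, universe, universe)$p_value, 1)
  expect_equal(overlap_test(universe[1:5], universe[6:10], universe)$p_value,
               1, tolerance = 1e-12)
  expect_error(overlap_test(c("zz"), b, universe), "subsets")
})

test_that("overlap p-value is monotone in the overlap count", {
  universe <- sprintf("g%02d", 1:50)
  ps <- vapply(0:10, function(k) {
    a <- universe[1:10]
    b <- c(universe[seq_len(k)], universe[30:(39 - k)])[1:10]
    overlap_test(a, b, universe)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("hub matching pairs persistent modules", {
  universe <- sprintf("v%02d", 1:40)
  clusters_a <- list(c1 = universe[1:12], c2 = universe[13:24])
  clusters_b <- list(k1 = universe[c(1:10, 30, 31)], k2 = universe[25:36])
  hubs_a <- list(c1 = universe[1], c2 = universe[13])
  hubs_b <- list(k1 = universe[1], k2 = universe[25])

  m <- match_clusters_by_hub(clusters_a, clusters_b, hubs_a, hubs_b, universe)
  expect_equal(nrow(m), 1)
  expect_equal(m$cluster_a, "c1")
  expect_equal(m$cluster_b, "k1")
  expect_lt(m$p_value, 0.001)

  # no shared hubs: empty pairing
  m0 <- match_clusters_by_hub(clusters_a, clusters_b,
                              list(c1 = "v05", c2 = "v15"),
                              list(k1 = "v31", k2 = "v25"), universe)
  expect_equal(nrow(m0), 0)
})

test_that("persistent planted modules are matched across inferred networks", {
  # the same 12-node module planted in two independently generated graphs
  module <- sprintf("v%02d", 1:12)
  others <- sprintf("v%02d", 13:40)
  universe <- c(module, others)
  build <- function(seed) {
    # v01 is wired to every module member, so the module's hub identity is
    # shared across the two networks by construction
    cmb <- t(combn(module[-1], 2))
    keep <- omicfuse:::with_seed(seed, runif(nrow(cmb)) < 0.6)
    bg <- t(combn(others, 2))
    keep_bg <- omicfuse:::with_seed(seed + 1, runif(nrow(bg)) < 0.08)
    edges <- rbind(
      data.frame(from = module[1], to = module[-1], weight = 1,
                 estimator = "ggm:x", stringsAsFactors = FALSE),
      data.frame(from = cmb[keep, 1], to = cmb[keep, 2], weight = 1,
                 estimator = "ggm:x", stringsAsFactors = FALSE),
      data.frame(from = bg[keep_bg, 1], to = bg[keep_bg, 2], weight = 1,
                 estimator = "ggm:x", stringsAsFactors = FALSE),
      # sparse module-background links keep the graph in one component
      data.frame(from = c("v02", "v06", "v11"),
                 to = c("v13", "v20", "v30"), weight = 1,
                 estimator = "ggm:x", stringsAsFactors = FALSE)
    )
    new_network(data.frame(name = universe, block = "x"), edges)
  }
  g1 <- build(101); g2 <- build(301)
  p1 <- spinglass_cluster(g1, seed = 1)
  p2 <- spinglass_cluster(g2, seed = 2)
  m1 <- cluster_members(p1); m2 <- cluster_members(p2)
  h1 <- extract_hubs(g1, p1$assignment)
  h2 <- extract_hubs(g2, p2$assignment)
  mm <- match_clusters_by_hub(m1, m2, h1, h2, universe)
  planted <- mm[vapply(seq_len(nrow(mm)), function(i) {
    length(intersect(m1[[mm$cluster_a[i]]], module)) >= 10 &&
      length(intersect(m2[[mm$cluster_b[i]]], module)) >= 10
  }, logical(1)), ]
  expect_gte(nrow(planted), 1)
  expect_lt(min(planted$p_value), 0.001)
})

test_that("gene-set enrichment flags the perfect set and drops disjoint ones", {
  background <- sprintf("gene%03d", 1:60)
  cluster <- background[1:12]
  sets <- list(
    perfect = cluster,
    random = background[c(5, 20, 30, 40, 50)],
    outside = c("foo", "bar")
  )
  expect_warning(res <- geneset_enrichment(cluster, sets, background),
                 "disjoint")
  expect_equal(nrow(res), 2)
  expect_equal(res$set[which.min(res$p_value)], "perfect")
  expect_true(all(res$q_value >= res$p_value))
  expect_error(geneset_enrichment(c("nope"), sets, background), "subset")
  expect_error(geneset_enrichment(cluster, sets, character(0)), "non-empty")
})

test_that("enrichment q-values are calibrated under the null", {
  background <- sprintf("gene%03d", 1:100)
  seeds <- omicfuse:::derive_seeds(99, 200)
  false_hits <- vapply(seq_len(200), function(r) {
    drawn <- omicfuse:::with_seed(seeds[r], {
      sets <- lapply(1:20, function(i) sample(background, 15))
      names(sets) <- paste0("s", 1:20)
      cl <- sample(background, 15)
      list(sets = sets, cl = cl)
    })
    res <- geneset_enrichment(drawn$cl, drawn$sets, background)
    any(res$q_value < 0.05)
  }, logical(1))
  expect_lte(mean(false_hits), 0.07)
})

test_that("GMT files round-trip gene sets", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c(
    "setA\tdesc\tg1\tg2\tg3",
    "setB\tanother\tg2\tg4"
  ), path)
  sets <- read_gmt(path)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_error(read_gmt({
    p2 <- tempfile(); writeLines("bad\tline", p2); p2
  }), "malformed")
})
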