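#' Configuration for an end-to-end network-inference run
#'
#' @param sim A [simulation_config()] used when `blocks` is `NULL`.
#' @param blocks Optional list of [omics_block()]s to analyze instead of
#'   simulating.
#' @param budgets Optional named integer vector of edge budgets per block
#'   (intra) -- defaults to each block's node count; pair budgets are always
#'   the summed node counts.
#' @param ncomp Canonical dimensions for the cross-block step. Default 3.
#' @param grid Ridge grid for [select_regularization()]; `NULL` skips
#'   cross-validation and uses `lam_fixed`.
#' @param lam_fixed Ridge weight used for both blocks when `grid` is `NULL`.
#'   Default 0.1.
#' @param folds Cross-validation folds. Default 5.
#' @param spins,gamma,t_start,t_stop,cool Passed to [spinglass_cluster()].
#' @param B Permutation replicates for both significance tests. Default 100.
#' @param swap_factor Attempted swaps per edge in the rewiring null.
#' @param alpha Significance level. Default 0.05.
#' @param gene_sets Optional named list of gene sets (or a GMT path) tested
#'   against the clusters of the block named by `geneset_block`.
#' @param geneset_block Block whose variables form the enrichment
#'   background. Default `"mrna"`.
#' @param seed Master seed for the run.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = simulation_config(), blocks = NULL,
                       budgets = NULL, ncomp = 3L, grid = NULL,
                       lam_fixed = 0.1, folds = 5L, spins = 25L, gamma = 1,
                       t_start = 1, t_stop = 0.01, cool = 0.99, B = 100L,
                       swap_factor = 10L, alpha = 0.05, gene_sets = NULL,
                       geneset_block = "mrna", seed = 1L) {
  structure(
    list(sim = sim, blocks = blocks, budgets = budgets, ncomp = ncomp,
         grid = grid, lam_fixed = lam_fixed, folds = folds, spins = spins,
         gamma = gamma, t_start = t_start, t_stop = t_stop, cool = cool,
         B = B, swap_factor = swap_factor, alpha = alpha,
         gene_sets = gene_sets, geneset_block = geneset_block,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full multi-omics network pipeline
#'
#' Executes simulate (or load) -> per-variable log-transform gate ->
#' centering -> intra-block sparse GGM networks (edge budget = node count)
#' -> pairwise regularized CCA relevance networks (budget = summed node
#' count) -> merge -> spin-glass clustering -> modularity and per-cluster
#' betweenness permutation tests -> hub extraction (-> gene-set enrichment
#' if gene sets are supplied) -> export. All artifacts are written under
#' `out_dir` together with a JSON manifest (config, seed, package version,
#' per-stage summaries, file checksums).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results (`global`
#'   network, `partition`, `modularity_test`, `betweenness`, `hubs`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("omicfuse_run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] seed=%d elapsed=%.1fs %s", stage, config$seed,
                    proc.time()[["elapsed"]] - t0, paste(...)))
  }

  # --- data -----------------------------------------------------------
  if (is.null(config$blocks)) {
    sim <- sample_multiblock(config$sim)
    blocks <- sim$blocks
    cohort <- simulate_weight_trajectories(
      config$sim$n_subjects, config$sim$group_probs, config$sim$seed
    )
    write_ground_truth(sim$truth, file.path(out_dir, "ground_truth.json"))
    write.table(cohort, file.path(out_dir, "cohort.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    stages$data <- list(source = "simulated",
                        groups = as.list(table(cohort$group_label)))
  } else {
    blocks <- config$blocks
    stages$data <- list(source = "supplied")
  }
  log_stage("data", length(blocks), "blocks")

  # --- preprocess ------------------------------------------------------
  reports <- list()
  for (b in seq_along(blocks)) {
    tr <- transform_block(blocks[[b]])
    blocks[[b]] <- center_by_batch(tr$block)
    reports[[blocks[[b]]$block_label]] <- tr$report
    write_block(blocks[[b]],
                file.path(out_dir, paste0(blocks[[b]]$block_label, ".tsv")))
  }
  all_reports <- do.call(rbind, reports)
  write.table(all_reports, file.path(out_dir, "transform_report.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  stages$preprocess <- list(
    transformed = sum(all_reports$transformed),
    variables = nrow(all_reports)
  )
  log_stage("preprocess", stages$preprocess$transformed, "vars transformed")

  # --- intra-block networks -------------------------------------------
  intra <- list()
  for (blk in blocks) {
    p <- ncol(blk$data)
    budget <- config$budgets[[blk$block_label]] %||% p
    g <- build_intra_network(blk, budget = budget)
    intra[[blk$block_label]] <- g
    log_stage("intra", blk$block_label, ":", igraph::ecount(g), "edges")
  }
  stages$intra <- lapply(intra, igraph::ecount)

  # --- inter-block networks -------------------------------------------
  nb <- length(blocks)
  inter <- list()
  pair_seeds <- derive_seeds(config$seed + 1L, nb * (nb - 1L) / 2L)
  pi <- 0L
  for (a in seq_len(nb - 1L)) {
    for (b2 in seq((a + 1L), nb)) {
      pi <- pi + 1L
      X <- blocks[[a]]; Y <- blocks[[b2]]
      if (!is.null(config$grid)) {
        sel <- select_regularization(X, Y, grid = config$grid,
                                     folds = config$folds,
                                     seed = pair_seeds[pi])
        lx <- sel$lam_x; ly <- sel$lam_y
      } else {
        lx <- ly <- config$lam_fixed
      }
      fit <- fit_rcca(X, Y, lam_x = lx, lam_y = ly, ncomp = config$ncomp)
      M <- relevance_matrix(fit, X, Y)
      g <- build_inter_network(M)
      nm <- paste(X$block_label, Y$block_label, sep = "-")
      inter[[nm]] <- g
      log_stage("inter", nm, ":", igraph::ecount(g), "edges,",
                sprintf("lam=(%.3g, %.3g)", lx, ly))
    }
  }
  stages$inter <- lapply(inter, igraph::ecount)

  # --- merge ----------------------------------------------------------
  global <- merge_networks(c(intra, inter))
  degs <- degree_table(global)
  write.table(degs$nodes, file.path(out_dir, "degrees.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  stages$merge <- list(nodes = igraph::vcount(global),
                       edges = igraph::ecount(global),
                       block_density = degs$block_density$density)
  log_stage("merge", igraph::vcount(global), "nodes,",
            igraph::ecount(global), "edges")

  # --- clustering and significance ------------------------------------
  modsig <- modularity_significance(
    global, B = config$B, seed = config$seed + 2L,
    swap_factor = config$swap_factor, spins = config$spins,
    gamma = config$gamma, t_start = config$t_start,
    t_stop = config$t_stop, cool = config$cool
  )
  part <- modsig$partition
  write.table(
    data.frame(node = names(part$assignment), cluster = part$assignment),
    file.path(out_dir, "partition.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE
  )
  write_null_ensemble(modsig$null,
                      file.path(out_dir, "modularity_null.json"))
  stages$community <- list(q = part$q, clusters = part$n_clusters,
                           significant = modsig$significant,
                           p_value = modsig$p_value)
  log_stage("cluster", part$n_clusters, "clusters, Q =",
            sprintf("%.3f", part$q),
            if (modsig$significant) "(significant)" else "(ns)")

  # --- per-cluster betweenness ----------------------------------------
  members <- cluster_members(part)
  bw_seeds <- derive_seeds(config$seed + 3L, length(members))
  bw <- list()
  for (ci in seq_along(members)) {
    sub <- igraph::induced_subgraph(global, members[[ci]])
    rep <- betweenness_significance(sub, B = config$B,
                                    seed = bw_seeds[ci],
                                    swap_factor = config$swap_factor,
                                    alpha = config$alpha)
    rep$cluster <- names(members)[ci]
    bw[[ci]] <- rep
  }
  bw <- do.call(rbind, bw)
  write.table(bw, file.path(out_dir, "betweenness.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  stages$betweenness <- list(significant = sum(bw$significant))
  log_stage("betweenness", sum(bw$significant), "significant nodes")

  # --- hubs & enrichment ----------------------------------------------
  hubs <- extract_hubs(global, part$assignment)
  stages$hubs <- hubs
  enrich <- NULL
  gene_sets <- config$gene_sets
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  if (!is.null(gene_sets)) {
    background <- igraph::V(global)$name[
      igraph::V(global)$block == config$geneset_block
    ]
    enrich <- do.call(rbind, lapply(names(members), function(cl) {
      genes <- intersect(members[[cl]], background)
      if (length(genes) == 0) return(NULL)
      res <- geneset_enrichment(genes, gene_sets, background)
      if (nrow(res)) res$cluster <- cl
      res
    }))
    if (!is.null(enrich)) {
      write.table(enrich, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    }
    log_stage("enrich", if (is.null(enrich)) 0 else nrow(enrich), "tests")
  }

  # --- export ----------------------------------------------------------
  glob_out <- global
  glob_out <- igraph::set_vertex_attr(glob_out, "cluster",
                                      value = unname(part$assignment))
  bwv <- stats::setNames(bw$betweenness, bw$node)[igraph::V(glob_out)$name]
  bpv <- stats::setNames(bw$p_value, bw$node)[igraph::V(glob_out)$name]
  glob_out <- igraph::set_vertex_attr(glob_out, "betweenness",
                                      value = unname(bwv))
  glob_out <- igraph::set_vertex_attr(glob_out, "betweenness_p",
                                      value = unname(bpv))
  write_network(glob_out, file.path(out_dir, "global.graphml"), "graphml")
  write_network(glob_out, file.path(out_dir, "global.gexf"), "gexf")
  for (nm in names(intra)) {
    write_network(intra[[nm]], file.path(out_dir, paste0("intra_", nm, ".graphml")))
  }
  for (nm in names(inter)) {
    write_network(inter[[nm]], file.path(out_dir, paste0("inter_", nm, ".graphml")))
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(packageVersion("omicfuse")),
    seed = config$seed,
    config = config_summary(config),
    stages = stages,
    source_networks = c(names(intra), names(inter)),
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log_stage("done", "outputs in", out_dir)
  invisible(list(global = glob_out, partition = part,
                 modularity_test = modsig, betweenness = bw, hubs = hubs,
                 enrichment = enrich, manifest = manifest,
                 out_dir = out_dir))
}

config_summary <- function(config) {
  out <- unclass(config)
  out$blocks <- if (is.null(out$blocks)) NULL else
    lapply(out$blocks, function(b) dim(b$data))
  out$gene_sets <- if (is.null(out$gene_sets)) NULL else
    length(out$gene_sets)
  out$sim <- unclass(out$sim)
  out
}
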