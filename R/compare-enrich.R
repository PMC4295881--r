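#' One-sided Fisher exact overlap test between two node sets
#'
#' Tests whether two sets drawn from a common universe share more members
#' than expected by chance: the p-value is the hypergeometric upper-tail
#' probability of at least the observed overlap given the set sizes and the
#' universe size (equivalently, the one-sided Fisher exact test on the 2x2
#' table).
#'
#' @param a,b Character vectors of node names, subsets of `universe`.
#' @param universe Character vector, the reference set.
#' @return A list of class `overlap_test`: `overlap`, `table` (both, a-only,
#'   b-only, neither), `p_value`, sizes.
#' @export
overlap_test <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  if (!all(a %in% universe) || !all(b %in% universe)) {
    stop_invalid("a and b must be subsets of the universe")
  }
  N <- length(universe)
  both <- length(intersect(a, b))
  tab <- c(
    both = both,
    a_only = length(a) - both,
    b_only = length(b) - both,
    neither = N - length(union(a, b))
  )
  p <- phyper(both - 1, length(a), N - length(a), length(b),
              lower.tail = FALSE)
  structure(
    list(overlap = both, table = tab, p_value = p,
         n_a = length(a), n_b = length(b), n_universe = N),
    class = "overlap_test"
  )
}

#' Match clusters across two networks by shared hubs
#'
#' Pairs every cluster of one partition with every cluster of the other
#' whose hub sets intersect, and forwards each pair to [overlap_test()] with
#' the full variable set as universe -- the test for whether a module
#' persists across conditions.
#'
#' @param clusters_a,clusters_b Named lists of node-name sets (cluster
#'   memberships of the two networks).
#' @param hubs_a,hubs_b Named lists of hub names per cluster (see
#'   [extract_hubs()]); names must match `clusters_*`.
#' @param universe Character vector of all variables.
#' @return A data.frame: `cluster_a`, `cluster_b`, `shared_hubs`, `overlap`,
#'   `p_value`. Zero rows if no hub is shared.
#' @export
match_clusters_by_hub <- function(clusters_a, clusters_b, hubs_a, hubs_b,
                                  universe) {
  stopifnot(identical(names(clusters_a), names(hubs_a)),
            identical(names(clusters_b), names(hubs_b)))
  rows <- list()
  for (i in names(clusters_a)) {
    for (j in names(clusters_b)) {
      shared <- intersect(hubs_a[[i]], hubs_b[[j]])
      if (length(shared) == 0) next
      ot <- overlap_test(clusters_a[[i]], clusters_b[[j]], universe)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_a = i, cluster_b = j,
        shared_hubs = paste(shared, collapse = ";"),
        overlap = ot$overlap, p_value = ot$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_a = character(0), cluster_b = character(0),
               shared_hubs = character(0), overlap = integer(0),
               p_value = numeric(0), stringsAsFactors = FALSE)
}

#' Gene-set over-representation for a cluster's genes
#'
#' Fisher exact enrichment of each collection set within the cluster's
#' genes, against a fixed background panel (the reference is the assayed
#' gene panel, not the genome). Collection sets are intersected with the
#' background first; sets with empty intersection are dropped with a
#' warning. P-values are Benjamini-Hochberg corrected across all tested
#' sets.
#'
#' @param cluster_genes Character vector, subset of `background`.
#' @param collections Named list of gene sets (e.g. from [read_gmt()]).
#' @param background Character vector, the gene panel.
#' @return A data.frame: `set`, `set_size` (within background), `overlap`,
#'   `p_value`, `q_value`.
#' @export
geneset_enrichment <- function(cluster_genes, collections, background) {
  background <- unique(background)
  if (length(background) == 0) stop_invalid("background must be non-empty")
  if (!all(cluster_genes %in% background)) {
    stop_invalid("cluster_genes must be a subset of the background")
  }
  trimmed <- lapply(collections, intersect, background)
  empty <- vapply(trimmed, length, integer(1)) == 0
  if (any(empty)) {
    warning(sprintf("%d collection set(s) disjoint from background dropped",
                    sum(empty)), call. = FALSE)
    trimmed <- trimmed[!empty]
  }
  if (length(trimmed) == 0) {
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, lapply(names(trimmed), function(nm) {
    ot <- overlap_test(cluster_genes, trimmed[[nm]], background)
    data.frame(set = nm, set_size = length(trimmed[[nm]]),
               overlap = ot$overlap, p_value = ot$p_value,
               stringsAsFactors = FALSE)
  }))
  res$q_value <- bh_adjust(res$p_value)
  res
}

#' Read gene sets from a GMT file
#'
#' Tab-delimited, one set per line: set name, description, then member
#' genes.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop_invalid("malformed GMT line: ", parts[1])
    unique(parts[-c(1, 2)])
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Cluster memberships as a named list
#'
#' Convenience converter from a partition to the node-set list consumed by
#' [match_clusters_by_hub()].
#'
#' @param partition An `omic_partition` (or named assignment vector).
#' @return Named list `cluster_<id>` -> character vector of node names.
#' @export
cluster_members <- function(partition) {
  assignment <- if (inherits(partition, "omic_partition")) {
    partition$assignment
  } else {
    partition
  }
  out <- split(names(assignment), assignment)
  names(out) <- paste0("cluster_", names(out))
  out
}
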