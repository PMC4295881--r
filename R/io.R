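#' Read a subject-by-variable matrix from delimited text
#'
#' Expects a header row and a leading subject-id column. Files stored
#' variable-major (variables in rows, as deposited expression tables often
#' are) are transposed with `orientation = "variables"`. Any cell that does
#' not parse as a number -- including `NA` -- is a parse error naming the
#' cell; duplicate variable names are an error.
#'
#' @param path Path to the file.
#' @param block_label Block label for the resulting [omics_block()].
#' @param orientation `"subjects"` (rows are subjects, default) or
#'   `"variables"` (rows are variables; transposed on read).
#' @param sep Field separator. Default tab.
#' @return An [omics_block()].
#' @export
read_matrix <- function(path, block_label = "block",
                        orientation = c("subjects", "variables"),
                        sep = "\t") {
  orientation <- match.arg(orientation)
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  ids <- raw[[1]]
  vn <- colnames(raw)[-1] # before subsetting: `[.data.frame` uniquifies
  cells <- as.matrix(raw[, -1, drop = FALSE])
  colnames(cells) <- vn
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_invalid(sprintf(
      "non-numeric cell at row %d, column '%s' (value '%s')",
      bad[1, 1], colnames(cells)[bad[1, 2]], cells[bad[1, , drop = FALSE]]
    ))
  }
  dimnames(num) <- list(ids, colnames(cells))
  if (orientation == "variables") num <- t(num)
  if (anyDuplicated(colnames(num))) {
    stop_invalid("duplicate variable names in ", path)
  }
  omics_block(num, block_label)
}

# Ensure the exported node/edge attributes exist (missing ones are written
# as explicit nulls, not omitted, so downstream schemas stay stable).
complete_attributes <- function(g) {
  for (a in c("block")) {
    if (!a %in% igraph::vertex_attr_names(g)) {
      g <- igraph::set_vertex_attr(g, a, value = NA_character_)
    }
  }
  if (!"degree" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::set_vertex_attr(g, "degree", value = igraph::degree(g))
  }
  for (a in c("betweenness", "betweenness_p")) {
    if (!a %in% igraph::vertex_attr_names(g)) {
      g <- igraph::set_vertex_attr(g, a, value = NA_real_)
    }
  }
  if (!"cluster" %in% igraph::vertex_attr_names(g)) {
    g <- igraph::set_vertex_attr(g, "cluster", value = NA_integer_)
  }
  if (igraph::ecount(g) > 0) {
    if (!"weight" %in% igraph::edge_attr_names(g)) {
      g <- igraph::set_edge_attr(g, "weight", value = NA_real_)
    }
    if (!"sign" %in% igraph::edge_attr_names(g)) {
      g <- igraph::set_edge_attr(
        g, "sign", value = ifelse(igraph::E(g)$weight >= 0, 1L, -1L)
      )
    }
    if (!"estimator" %in% igraph::edge_attr_names(g)) {
      g <- igraph::set_edge_attr(g, "estimator", value = NA_character_)
    }
  }
  g
}

#' Write a network to GraphML or GEXF
#'
#' Both formats carry node attributes (`block`, `degree`, `betweenness`,
#' `betweenness_p`, `cluster`) and edge attributes (`weight`, `sign`,
#' `estimator`) for force-based layout in external viewers. Attributes not
#' yet computed are written as explicit nulls. GraphML goes through
#' [igraph::write_graph()]; GEXF 1.2 is emitted directly.
#'
#' @param g A network.
#' @param path Output file.
#' @param format `"graphml"` or `"gexf"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, format = c("graphml", "gexf")) {
  format <- match.arg(format)
  g <- complete_attributes(g)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_gexf(g, path)
  }
  invisible(path)
}

#' Read a network from GraphML
#'
#' @param path Path to a GraphML file written by [write_network()].
#' @return An `igraph` network.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

# Minimal GEXF 1.2 writer (undirected, static graph).
write_gexf <- function(g, path) {
  node_attrs <- data.frame(
    id = c("block", "degree", "betweenness", "betweenness_p", "cluster"),
    type = c("string", "double", "double", "double", "integer"),
    stringsAsFactors = FALSE
  )
  edge_attrs <- data.frame(
    id = c("weight", "sign", "estimator"),
    type = c("double", "integer", "string"),
    stringsAsFactors = FALSE
  )
  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://www.gexf.net/1.2draft", version = "1.2"
  )
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected",
                               mode = "static")
  fmt <- function(v) {
    if (is.na(v)) "" else if (is.numeric(v)) {
      format(v, digits = 15, scientific = FALSE, trim = TRUE)
    } else {
      as.character(v)
    }
  }
  add_attr_decl <- function(parent, class, attrs) {
    decl <- xml2::xml_add_child(parent, "attributes", class = class)
    for (i in seq_len(nrow(attrs))) {
      xml2::xml_add_child(decl, "attribute", id = attrs$id[i],
                          title = attrs$id[i], type = attrs$type[i])
    }
  }
  add_attr_decl(graph, "node", node_attrs)
  add_attr_decl(graph, "edge", edge_attrs)

  nodes <- xml2::xml_add_child(graph, "nodes")
  for (v in seq_len(igraph::vcount(g))) {
    nd <- xml2::xml_add_child(nodes, "node",
                              id = igraph::V(g)$name[v],
                              label = igraph::V(g)$name[v])
    av <- xml2::xml_add_child(nd, "attvalues")
    for (a in node_attrs$id) {
      val <- igraph::vertex_attr(g, a)[v]
      xml2::xml_add_child(av, "attvalue", `for` = a, value = fmt(val))
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g))
    for (e in seq_len(igraph::ecount(g))) {
      ed <- xml2::xml_add_child(edges, "edge", id = as.character(e - 1L),
                                source = ends[e, 1], target = ends[e, 2])
      av <- xml2::xml_add_child(ed, "attvalues")
      for (a in edge_attrs$id) {
        val <- igraph::edge_attr(g, a)[e]
        xml2::xml_add_child(av, "attvalue", `for` = a, value = fmt(val))
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
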