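# Graph export: igraph conversions, GraphML / DOT writers and flat
# edge-list CSVs.

#' Convert a network to an igraph object
#'
#' @param x a [BayesNet-class] or [ConsensusNetwork-class]. Consensus edges
#'   carry `frequency`, `meanIS` and `mutual` attributes.
#' @return An [igraph::igraph] directed graph.
#' @export
asIgraph <- function(x) {
  if (is(x, "BayesNet")) {
    g <- igraph::make_empty_graph(directed = TRUE) +
      igraph::vertices(x@nodes)
    if (nrow(x@edges))
      g <- igraph::add_edges(g, t(matrix(match(x@edges, x@nodes),
                                         ncol = 2)))
    return(g)
  }
  if (is(x, "ConsensusNetwork")) {
    e <- x@edges
    nodes <- sort(unique(c(e$parent, e$child)))
    e$mutual <- as.integer(e$mutual)  # 0/1: DOT has no boolean attributes
    g <- igraph::graph_from_data_frame(
      e[, c("parent", "child", "frequency", "meanIS", "mutual")],
      directed = TRUE, vertices = nodes)
    return(g)
  }
  stop("cannot convert object of class ", class(x)[1])
}

#' Write a network as GraphML
#'
#' @param x a [BayesNet-class] or [ConsensusNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(x, path) {
  igraph::write_graph(asIgraph(x), path, format = "graphml")
  invisible(path)
}

#' Write a network as Graphviz DOT
#'
#' @inheritParams writeGraphML
#' @return `path`, invisibly.
#' @export
writeDOT <- function(x, path) {
  igraph::write_graph(asIgraph(x), path, format = "dot")
  invisible(path)
}

#' Write a consensus network as a flat edge list
#'
#' Columns: parent, child, frequency, is (mean influence score), mutual.
#'
#' @param x a [ConsensusNetwork-class].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(x, path) {
  stopifnot(is(x, "ConsensusNetwork"))
  e <- x@edges
  out <- data.frame(parent = e$parent, child = e$child,
                    frequency = e$frequency, is = e$meanIS,
                    mutual = e$mutual)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
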