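#' Confidence filter for PPI edges
#'
#' Keeps edges with confidence at or above `minConf` (inclusive, matching
#' the usual "combined score >= 0.7" criterion for high-confidence STRING
#' interactions).
#'
#' @param edges canonical edge data.frame (see [readPPIEdges()]).
#' @param minConf inclusive confidence threshold.
#' @return filtered edge data.frame.
#' @export
filterEdges <- function(edges, minConf = 0.7) {
  out <- edges[edges$confidence >= minConf, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Induced PPI subnetwork on a protein set
#'
#' Builds the subgraph induced by `nodes` on a (typically
#' confidence-filtered) edge list.  Isolated nodes are retained and
#' flagged; connected components and degrees are computed.
#'
#' @param nodes character vector of symbols, or a reversal-hit table with a
#'   `gene` column (and optionally `class`, carried onto the nodes).
#' @param edges canonical edge data.frame.
#' @return classed list (`Subnetwork`) with `nodes` (data.frame `gene`,
#'   `degree`, `component`, `isolated`, optional `class`), `edges`
#'   (data.frame restricted to the node set), `components` (list of node
#'   vectors, largest first) and `n_components`.
#' @export
inducedSubnetwork <- function(nodes, edges) {
  cls <- NULL
  if (is.data.frame(nodes)) {
    if ("class" %in% colnames(nodes))
      cls <- setNames(nodes$class, toupper(nodes$gene))
    nodes <- nodes$gene
  }
  nodes <- unique(toupper(nodes))
  sub <- edges[edges$protein_a %in% nodes & edges$protein_b %in% nodes, ,
               drop = FALSE]
  rownames(sub) <- NULL
  g <- igraph::graph_from_data_frame(
    sub[c("protein_a", "protein_b")], directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  nodeTab <- data.frame(gene = nodes,
                        degree = as.integer(deg[nodes]),
                        component = as.integer(comp$membership[nodes]),
                        isolated = as.integer(deg[nodes]) == 0L,
                        stringsAsFactors = FALSE)
  if (!is.null(cls)) nodeTab$class <- unname(cls[nodeTab$gene])
  compList <- split(nodeTab$gene, nodeTab$component)
  compList <- compList[order(-lengths(compList))]
  names(compList) <- NULL
  structure(list(nodes = nodeTab, edges = sub,
                 components = lapply(compList, sort),
                 n_components = comp$no),
            class = "Subnetwork")
}

#' @export
print.Subnetwork <- function(x, ...) {
  cat(sprintf("Subnetwork: %d nodes (%d isolated), %d edges, %d components\n",
              nrow(x$nodes), sum(x$nodes$isolated), nrow(x$edges),
              x$n_components))
  invisible(x)
}

#' Hub proteins of a subnetwork
#'
#' @param subnet a `Subnetwork` from [inducedSubnetwork()].
#' @param k number of hubs.
#' @return the `k` highest-degree nodes, ties broken lexicographically.
#' @export
topHubs <- function(subnet, k = 10) {
  nt <- subnet$nodes
  nt <- nt[order(-nt$degree, nt$gene), , drop = FALSE]
  head(nt, k)
}
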