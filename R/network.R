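#' Local descriptors of a protein-interaction network
#'
#' Node count, edge count, average node degree and average local
#' clustering coefficient of an undirected simple graph given as an edge
#' list. Duplicate edges (in either orientation) are collapsed;
#' self-loops are rejected. When a node list is supplied, isolated nodes
#' count toward the node set with degree 0, and an edge naming an
#' undeclared node is an error. Nodes of degree < 2 contribute a local
#' clustering coefficient of 0 to the average (the inclusive convention;
#' excluding them would change the average, so the convention is recorded
#' in the result).
#'
#' @param edge_list Two-column `data.frame`/`data.table` (`from`, `to`)
#'   of undirected edges.
#' @param node_list Optional character vector declaring the node set;
#'   default is the nodes named by the edges.
#' @return A list with `nodes`, `edges`, `average_degree`
#'   (`2 * edges / nodes`), `average_local_clustering` and
#'   `clustering_convention`.
#' @export
graph_summary <- function(edge_list, node_list = NULL) {
  el <- as.data.table(edge_list)
  if (nrow(el) > 0) {
    setnames(el, 1:2, c("from", "to"))
    el[, `:=`(from = as.character(from), to = as.character(to))]
    if (any(el$from == el$to))
      stop("self-loop(s) in edge list: ",
           paste(head(unique(el$from[el$from == el$to]), 5), collapse = ", "))
    # canonical orientation, then collapse duplicates
    swap <- el$from > el$to
    tmp <- el$from[swap]
    el$from[swap] <- el$to[swap]
    el$to[swap] <- tmp
    el <- unique(el[, .(from, to)])
  }
  nodes <- if (is.null(node_list)) {
    sort(unique(c(el$from, el$to)))
  } else {
    node_list <- as.character(node_list)
    if (anyDuplicated(node_list) > 0) stop("duplicate node(s) in node list")
    undeclared <- setdiff(unique(c(el$from, el$to)), node_list)
    if (length(undeclared))
      stop("edge(s) name undeclared node(s): ",
           paste(head(undeclared, 5), collapse = ", "))
    node_list
  }
  n <- length(nodes)
  e <- nrow(el)
  if (n == 0)
    return(list(nodes = 0L, edges = 0L, average_degree = 0,
                average_local_clustering = 0,
                clustering_convention = "degree < 2 counts as 0"))
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = nodes)
  lc <- igraph::transitivity(g, type = "local", isolates = "zero")
  list(nodes = n, edges = e,
       average_degree = 2 * e / n,
       average_local_clustering = mean(lc),
       clustering_convention = "degree < 2 counts as 0")
}

#' Induced subnetwork on selected symbols
#'
#' Restricts an edge list to the edges whose both endpoints belong to a
#' selection (e.g. the differential candidates from the frequency
#' comparison) and re-computes the summary on the induced subgraph.
#'
#' @param edge_list Two-column edge list.
#' @param selected_symbols Character vector of selected node names.
#' @return A list with `edge_list` (the induced edges) and `summary`
#'   (from [graph_summary()], over the selected nodes present in the
#'   original node set).
#' @export
subnetwork_by_selection <- function(edge_list, selected_symbols) {
  el <- as.data.table(edge_list)
  selected_symbols <- unique(as.character(selected_symbols))
  if (nrow(el) > 0) {
    setnames(el, 1:2, c("from", "to"))
    el[, `:=`(from = as.character(from), to = as.character(to))]
    keep_nodes <- intersect(unique(c(el$from, el$to)), selected_symbols)
    sub <- el[from %in% selected_symbols & to %in% selected_symbols]
  } else {
    keep_nodes <- character(0)
    sub <- el
  }
  list(edge_list = sub,
       summary = graph_summary(sub, node_list = keep_nodes))
}
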