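#' Coerce to an igraph object
#'
#' Accepts an igraph object (returned as-is after simplification checks),
#' a `cooc_network` from [filter_network()] (isolated nodes are kept), or
#' an edge-list data frame whose first two columns are the endpoints (an
#' optional `weight` column becomes an edge attribute). Self-loops and
#' multi-edges are collapsed so downstream metrics always see a simple
#' graph.
#'
#' @param x Graph-like object.
#' @return An undirected simple igraph object.
#' @export
as_conet_igraph <- function(x) {
  if (inherits(x, "igraph")) {
    g <- x
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    if (!igraph::is_simple(g)) g <- igraph::simplify(g, edge.attr.comb = "first")
    return(g)
  }
  if (inherits(x, "cooc_network")) {
    edges <- as.data.frame(x$edges)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = x$nodes))
    return(igraph::simplify(g, edge.attr.comb = "first"))
  }
  if (is.data.frame(x)) {
    if (ncol(x) < 2) abort("An edge-list data frame needs at least two columns.")
    g <- igraph::graph_from_data_frame(as.data.frame(x), directed = FALSE)
    return(igraph::simplify(g, edge.attr.comb = "first"))
  }
  abort("Cannot interpret `x` as a graph: supply an igraph, cooc_network or edge-list data frame.")
}

# Vertex identifiers: names when present, 1-based indices otherwise.
vertex_ids <- function(g) {
  if (!is.null(igraph::V(g)$name)) igraph::V(g)$name else as.character(seq_len(igraph::vcount(g)))
}

#' Extract the giant (largest connected) component
#'
#' Ties on component size are broken deterministically: the component
#' containing the smallest vertex identifier wins.
#'
#' @param graph Graph-like object (see [as_conet_igraph()]).
#' @return The induced igraph subgraph on the largest component.
#' @export
giant_component <- function(graph) {
  g <- as_conet_igraph(graph)
  if (igraph::vcount(g) == 0) abort("Cannot take the giant component of an empty graph.")
  comp <- igraph::components(g)
  winners <- which(comp$csize == max(comp$csize))
  if (length(winners) > 1) {
    ids <- vertex_ids(g)
    min_id <- vapply(winners, function(ci) min(ids[comp$membership == ci]), character(1))
    winners <- winners[order(min_id)][1]
  }
  igraph::induced_subgraph(g, which(comp$membership == winners[1]))
}

#' First-order graph summaries
#'
#' `graph_density()` is \eqn{2|E| / (|V|(|V|-1))}; `mean_degree()` is
#' \eqn{2|E|/|V|}; `degree_sequence()` tabulates per-node degrees.
#'
#' @param graph Graph-like object.
#' @return A number, or for `degree_sequence()` a tibble (`node`, `degree`).
#' @export
graph_density <- function(graph) {
  g <- as_conet_igraph(graph)
  n <- igraph::vcount(g)
  if (n < 2) abort("Density requires at least 2 nodes.")
  2 * as.double(igraph::ecount(g)) / (as.double(n) * (n - 1))
}

#' @rdname graph_density
#' @export
mean_degree <- function(graph) {
  g <- as_conet_igraph(graph)
  n <- igraph::vcount(g)
  if (n < 1) abort("Mean degree requires at least 1 node.")
  2 * as.double(igraph::ecount(g)) / n
}

#' @rdname graph_density
#' @export
degree_sequence <- function(graph) {
  g <- as_conet_igraph(graph)
  tibble(node = vertex_ids(g), degree = as.integer(igraph::degree(g)))
}

#' Descriptive statistics from node and edge counts
#'
#' Density and mean degree computed directly from printed `n` and `m`,
#' without materialising a graph; handy for comparing against reported
#' network summaries.
#'
#' @param n_nodes,n_edges Counts.
#' @return One-row tibble (`n_nodes`, `n_edges`, `density`, `mean_degree`).
#' @export
#' @examples
#' network_descriptives(26338, 19408276)
network_descriptives <- function(n_nodes, n_edges) {
  if (n_nodes < 1) abort("`n_nodes` must be >= 1.")
  tibble(
    n_nodes = n_nodes, n_edges = n_edges,
    density = if (n_nodes >= 2) 2 * as.double(n_edges) / (as.double(n_nodes) * (n_nodes - 1)) else NA_real_,
    mean_degree = 2 * as.double(n_edges) / n_nodes
  )
}
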