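#' Build a coexpression network from an edge list
#'
#' Undirected graph with positive mutual-information edge weights and
#' optional node annotations (`is_tf` flag, `log2fc`). Self-loops are
#' dropped with a warning; duplicate edges are collapsed keeping the
#' maximum weight.
#'
#' @param edges Tibble `node1`, `node2`, `mi` (mutual information > 0).
#' @param nodes Optional tibble `node`, `is_tf` (logical) and optionally
#'   `log2fc`; nodes absent from it default to `is_tf = FALSE`.
#' @return An igraph object of class `coexpression_network`.
#' @export
coexpression_network <- function(edges, nodes = NULL) {
  if (!all(c("node1", "node2", "mi") %in% names(edges))) {
    abort("`edges` needs columns node1, node2, mi.")
  }
  if (any(edges$mi <= 0)) abort("Mutual-information weights must be positive.")
  loops <- edges$node1 == edges$node2
  if (any(loops)) {
    warn(sprintf("Dropping %d self-loop(s).", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(mi = "max"))
  vn <- igraph::V(g)$name
  if (!is.null(nodes)) {
    idx <- match(vn, nodes$node)
    igraph::V(g)$is_tf <- ifelse(is.na(idx), FALSE, as.logical(nodes$is_tf[idx]))
    if ("log2fc" %in% names(nodes)) {
      igraph::V(g)$log2fc <- nodes$log2fc[idx]
    }
  } else {
    igraph::V(g)$is_tf <- FALSE
  }
  class(g) <- c("coexpression_network", class(g))
  g
}

#' First-neighbor subnetwork of a node
#'
#' Induced subgraph on a query node and its direct neighbors, preserving
#' edge weights and node attributes (so edges among the neighbors are kept
#' too).
#'
#' @param net A `coexpression_network`.
#' @param node Node name.
#' @return The induced subgraph, still a `coexpression_network`.
#' @export
first_neighbors <- function(net, node) {
  if (!node %in% igraph::V(net)$name) {
    abort(paste0("Node not present in the network: ", node))
  }
  vs <- igraph::ego(net, order = 1, nodes = node)[[1]]
  sub <- igraph::induced_subgraph(net, vs)
  class(sub) <- c("coexpression_network", class(sub))
  sub
}

#' Betweenness centrality, normalized per component
#'
#' Shortest-path betweenness on unweighted paths (mutual information is a
#' coexpression strength, not a path cost), normalized within each
#' connected component by (n - 1)(n - 2) / 2 so values lie in \[0, 1\].
#' `weighted = TRUE` uses 1 / MI as edge length instead.
#'
#' @param net A `coexpression_network`.
#' @param weighted Use inverse mutual information as distances (default
#'   FALSE).
#' @return Tibble `node`, `betweenness`.
#' @export
node_betweenness <- function(net, weighted = FALSE) {
  comp <- igraph::components(net)
  out <- numeric(igraph::vcount(net))
  for (k in seq_len(comp$no)) {
    vs <- which(comp$membership == k)
    n <- length(vs)
    if (n < 3) {
      out[vs] <- 0
      next
    }
    sub <- igraph::induced_subgraph(net, vs)
    w <- if (weighted) 1 / igraph::E(sub)$mi else NA
    b <- igraph::betweenness(sub, directed = FALSE, weights = w)
    out[vs] <- b / ((n - 1) * (n - 2) / 2)
  }
  tibble(node = igraph::V(net)$name, betweenness = out)
}

#' Transcription-factor enrichment of a subnetwork
#'
#' One-sided hypergeometric upper-tail test of the TF count in a node set
#' against the whole network as background: with N background nodes, K of
#' them TFs and a subnetwork of n nodes containing k TFs, the p-value is
#' P(X >= k) for X hypergeometric(N, K, n).
#'
#' @param net A `coexpression_network` with an `is_tf` node attribute.
#' @param subnetwork Character vector of node names (or a
#'   `coexpression_network`, e.g. from [first_neighbors()], whose nodes are
#'   used).
#' @return One-row tibble `n_subnetwork`, `n_tf_subnetwork`,
#'   `n_background`, `n_tf_background`, `p_value`.
#' @export
tf_enrichment <- function(net, subnetwork) {
  if (inherits(subnetwork, "igraph")) subnetwork <- igraph::V(subnetwork)$name
  if (length(subnetwork) == 0) abort("`subnetwork` must be nonempty.")
  vn <- igraph::V(net)$name
  if (!all(subnetwork %in% vn)) {
    abort("All subnetwork nodes must belong to the network.")
  }
  is_tf <- as.logical(igraph::V(net)$is_tf)
  k <- sum(is_tf[match(subnetwork, vn)])
  n <- length(subnetwork)
  K <- sum(is_tf)
  N <- length(vn)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble(
    n_subnetwork = n, n_tf_subnetwork = k,
    n_background = N, n_tf_background = K, p_value = p
  )
}

#' Export a network as a TSV edge list
#'
#' @param net A `coexpression_network`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(net, path) {
  df <- igraph::as_data_frame(net, what = "edges")
  readr::write_tsv(
    tibble(node1 = df$from, node2 = df$to, mi = df$mi), path
  )
  invisible(path)
}
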