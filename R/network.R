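#' Build a similarity network from the k strongest gene pairs
#'
#' Ranks all defined off-diagonal gene pairs by similarity (descending),
#' breaking ties by lexicographic gene-pair order, and keeps exactly the
#' top `k` as undirected weighted edges. Nodes are the endpoints of the
#' retained edges, so every node has degree at least one; self-loops are
#' never produced.
#'
#' @param S A `gi_similarity`.
#' @param k Number of edges to retain (the conventional network size for
#'   a genome-scale screen is 20,000).
#' @return A `gi_network`: list with `graph` (an [igraph::graph] with a
#'   `weight` edge attribute) and `threshold_weight`, the weight of the
#'   rank-`k` edge.
#' @export
build_top_k_network <- function(S, k = 20000) {
  stopifnot(inherits(S, "gi_similarity"), k >= 1)
  ut <- upper.tri(S$values)
  keep <- ut & S$defined
  n_cand <- sum(keep)
  if (n_cand < k) {
    abort(sprintf("only %d defined candidate edges, fewer than k = %d", n_cand, k))
  }
  idx <- which(keep, arr.ind = TRUE)
  g1 <- S$gene_ids[idx[, 1]]
  g2 <- S$gene_ids[idx[, 2]]
  ga <- pmin(g1, g2)
  gb <- pmax(g1, g2)
  w <- S$values[keep]
  ord <- order(-w, ga, gb)
  sel <- ord[seq_len(k)]
  edges <- tibble(gene_a = ga[sel], gene_b = gb[sel], weight = w[sel])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  new_gi_network(g, threshold_weight = edges$weight[k])
}

new_gi_network <- function(graph, threshold_weight = NA_real_) {
  structure(list(graph = graph, threshold_weight = threshold_weight),
            class = "gi_network")
}

#' Construct a gene network from an edge table
#'
#' Mostly useful for tests and small examples; [build_top_k_network()]
#' is the normal entry point.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b` and
#'   optionally `weight` (defaults to 1).
#' @param threshold_weight Recorded cutoff weight, if known.
#' @return A `gi_network`.
#' @export
gi_network <- function(edges, threshold_weight = NA_real_) {
  edges <- as_tibble(edges)
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    abort("`edges` needs columns gene_a and gene_b")
  }
  if (!("weight" %in% names(edges))) edges$weight <- 1
  if (any(edges$gene_a == edges$gene_b)) abort("self-loops are not allowed")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (any(igraph::count_multiple(g) > 1)) abort("duplicate edges are not allowed")
  new_gi_network(g, threshold_weight)
}

#' @export
print.gi_network <- function(x, ...) {
  cat(sprintf("<gi_network> %d nodes, %d edges (threshold weight %s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              format(x$threshold_weight, digits = 4)))
  invisible(x)
}

#' Extract the giant connected component
#'
#' Returns the subnetwork induced by the connected component with the
#' most nodes. Smaller disconnected parts are discarded before module
#' detection. A size tie is broken deterministically in favour of the
#' component containing the lexicographically smallest node label.
#'
#' @param net A `gi_network`.
#' @return A `gi_network` restricted to the giant component.
#' @export
giant_component <- function(net) {
  stopifnot(inherits(net, "gi_network"))
  g <- net$graph
  if (igraph::vcount(g) == 0) abort("network is empty")
  comp <- igraph::components(g)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    firsts <- vapply(best, function(b) {
      min(igraph::V(g)$name[comp$membership == b])
    }, character(1))
    best <- best[order(firsts)[1]]
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == best))
  new_gi_network(sub, net$threshold_weight)
}

#' Node and edge counts for a network and its giant component
#'
#' @param net Full `gi_network`.
#' @param giant Its giant component (defaults to computing it).
#' @return One-row tibble with node/edge counts for both graphs and the
#'   threshold weight.
#' @export
network_summary <- function(net, giant = giant_component(net)) {
  tibble(
    nodes = igraph::vcount(net$graph),
    edges = igraph::ecount(net$graph),
    nodes_giant = igraph::vcount(giant$graph),
    edges_giant = igraph::ecount(giant$graph),
    threshold_weight = net$threshold_weight
  )
}

#' @export
glance.gi_network <- function(x, ...) network_summary(x)

#' @export
tidy.gi_network <- function(x, ...) {
  df <- igraph::as_data_frame(x$graph, what = "edges")
  swap <- df$from > df$to
  tmp <- df$from[swap]
  df$from[swap] <- df$to[swap]
  df$to[swap] <- tmp
  w <- if ("weight" %in% names(df)) df$weight else rep(1, nrow(df))
  tibble(gene_a = df$from, gene_b = df$to, weight = w) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Write / read an edge list as tab-separated text
#'
#' Three columns, `gene_a gene_b weight`, pairs in lexicographic order.
#'
#' @param net A `gi_network`.
#' @param path File path.
#' @return The network, invisibly (writer) or a `gi_network` (reader).
#' @export
write_edge_list <- function(net, path) {
  write.table(tidy(net), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(net)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  gi_network(read.delim(path, stringsAsFactors = FALSE))
}

#' Degree distribution plot
#'
#' @param object A `gi_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gi_network <- function(object, ...) {
  df <- tibble(degree = igraph::degree(object$graph))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "node degree", y = "number of genes")
}
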