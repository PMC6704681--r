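# Independent brute-force oracles used to check the package's fast paths.
# These deliberately share no code with the implementation.

# All shortest paths between two nodes, by explicit breadth-first layering
# and recursive path enumeration on an adjacency list.
enumerate_shortest_paths <- function(adj, from, to) {
  # BFS distances
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[from] <- 0
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) {
      if (is.infinite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  if (is.infinite(dist[to])) return(list())
  walk <- function(v) {
    if (v == from) return(list(from))
    preds <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
    out <- list()
    for (p in preds) {
      for (path in walk(p)) out[[length(out) + 1]] <- c(path, v)
    }
    out
  }
  walk(to)
}

# Edge betweenness by exhaustive shortest-path enumeration with equal
# splitting among tied paths. `edges` is a two-column character matrix.
brute_edge_betweenness <- function(edges) {
  nodes <- sort(unique(as.vector(edges)))
  adj <- setNames(lapply(nodes, function(v) {
    sort(unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])))
  }), nodes)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  scores <- setNames(rep(0, nrow(edges)), key(edges[, 1], edges[, 2]))
  if (length(nodes) < 2) return(scores)
  pairs <- combn(nodes, 2)
  for (p in seq_len(ncol(pairs))) {
    paths <- enumerate_shortest_paths(adj, pairs[1, p], pairs[2, p])
    if (length(paths) == 0) next
    w <- 1 / length(paths)
    for (path in paths) {
      for (i in seq_len(length(path) - 1)) {
        k <- key(path[i], path[i + 1])
        scores[k] <- scores[k] + w
      }
    }
  }
  scores
}

# Maximum assignment by exhaustive permutation search (square or
# rectangular; only feasible for tiny matrices).
brute_max_assignment <- function(M) {
  n <- max(dim(M))
  sq <- matrix(0, n, n)
  sq[seq_len(nrow(M)), seq_len(ncol(M))] <- M
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- -Inf
  for (p in perms(seq_len(n))) {
    tot <- sum(sq[cbind(seq_len(n), p)])
    if (tot > best) best <- tot
  }
  best
}

# Scalar-loop reference for all-pairs similarity of rows of a matrix.
loop_similarity_matrix <- function(m, fun) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- fun(m[i, ], m[j, ])
    }
  }
  out
}

# Random connected-ish test graph as a two-column character edge matrix.
random_edge_matrix <- function(n, p = 0.25) {
  labels <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(labels, 2))
  keep <- stats::runif(nrow(pairs)) < p
  # always keep a spanning path so the graph is connected
  path <- cbind(labels[-n], labels[-1])
  unique(rbind(pairs[keep, , drop = FALSE], path))
}

# Small deterministic screen configuration used across tests (kept light
# so the whole suite stays fast).
small_screen_config <- function(seed = 11, ...) {
  synthetic_config(
    n_modules = 4, module_size_range = c(5, 6), partners_per_module = 8,
    n_background_genes = 60, seed = seed, ...
  )
}

pipeline_k <- function(screen, multiplier = 5) {
  multiplier * sum(vapply(screen$truth_modules,
                          function(m) choose(length(m), 2), numeric(1)))
}
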