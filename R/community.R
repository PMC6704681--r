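#' Edge betweenness scores
#'
#' For every edge, the number of shortest paths between unordered node
#' pairs that run through it, with equal fractional splitting among tied
#' shortest paths. By default the graph is treated as unweighted: edge
#' weights in a similarity network mean closeness, so using them as path
#' lengths would invert their sense. With `weighted = TRUE`, `1/weight`
#' is used as the length of an edge.
#'
#' @param net A `gi_network`.
#' @param weighted Use `1/weight` as edge length instead of unit length.
#' @return Tibble with columns `gene_a`, `gene_b`, `betweenness`.
#' @export
edge_betweenness_scores <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "gi_network"))
  g <- net$graph
  w <- if (weighted) 1 / igraph::E(g)$weight else NA
  b <- igraph::edge_betweenness(g, directed = FALSE, weights = w)
  ends <- igraph::ends(g, igraph::E(g))
  tibble(
    gene_a = pmin(ends[, 1], ends[, 2]),
    gene_b = pmax(ends[, 1], ends[, 2]),
    betweenness = b
  )
}

#' Module detection by recursive edge-betweenness removal
#'
#' The Girvan-Newman procedure: repeatedly compute edge betweenness,
#' remove the single most-used edge, and continue until no edges remain.
#' Every connected component whose size falls within
#' `[min_size, max_size]` at any step — including the initial state — is
#' recorded as a module. The returned clustering solution is the
#' deduplicated union of all recorded modules; modules may be nested,
#' since a component recorded early may later fragment into smaller
#' recordable components.
#'
#' The 5-50 default range reflects the size span expected of functional
#' gene modules.
#'
#' @param net A `gi_network`.
#' @param min_size,max_size Inclusive bounds on recorded component sizes.
#' @param weighted Passed to [edge_betweenness_scores()].
#' @param prune Drop components that have fallen below `min_size` from
#'   further processing. No component can ever grow, so this does not
#'   change the result (a property checked in the test suite); it only
#'   speeds up the tail of the recursion.
#' @return A `gi_clustering`: list with `modules` (list of sorted gene
#'   vectors), `universe` (nodes of the input network), `min_size`,
#'   `max_size`.
#' @export
girvan_newman_clustering <- function(net, min_size = 5, max_size = 50,
                                     weighted = FALSE, prune = TRUE) {
  stopifnot(inherits(net, "gi_network"), min_size >= 1, max_size >= min_size)
  g <- net$graph
  universe <- sort(igraph::V(g)$name)
  seen <- new.env(parent = emptyenv())
  modules <- list()

  record <- function(g) {
    comp <- igraph::components(g)
    in_range <- which(comp$csize >= min_size & comp$csize <= max_size)
    for (ci in in_range) {
      genes <- sort(igraph::V(g)$name[comp$membership == ci])
      key <- paste(genes, collapse = "\r")
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        modules[[length(modules) + 1]] <<- genes
      }
    }
    comp
  }

  repeat {
    comp <- record(g)
    if (prune) {
      small <- which(comp$csize < min_size)
      if (length(small) > 0) {
        g <- igraph::induced_subgraph(g, which(!(comp$membership %in% small)))
      }
    }
    if (igraph::ecount(g) == 0) break
    w <- if (weighted) 1 / igraph::E(g)$weight else NA
    b <- igraph::edge_betweenness(g, directed = FALSE, weights = w)
    top <- which(b >= max(b) - 1e-9)
    if (length(top) > 1) {
      ends <- igraph::ends(g, igraph::E(g)[top])
      pa <- pmin(ends[, 1], ends[, 2])
      pb <- pmax(ends[, 1], ends[, 2])
      top <- top[order(pa, pb)[1]]
    }
    g <- igraph::delete_edges(g, igraph::E(g)[top])
  }

  gi_clustering(modules, universe, min_size, max_size)
}

#' Construct a clustering solution
#'
#' @param modules List of character vectors (gene sets); deduplicated as
#'   sets, each must fall within the size bounds and inside the universe.
#' @param universe Character vector: the gene universe the solution was
#'   derived from.
#' @param min_size,max_size Size bounds the modules were recorded under.
#' @return A `gi_clustering`.
#' @export
gi_clustering <- function(modules, universe, min_size = 5, max_size = 50) {
  modules <- lapply(modules, function(m) sort(unique(as.character(m))))
  sizes <- lengths(modules)
  if (any(sizes < min_size | sizes > max_size)) {
    abort("every module size must lie within [min_size, max_size]")
  }
  if (length(modules) > 0) {
    keys <- vapply(modules, paste, character(1), collapse = "\r")
    modules <- modules[!duplicated(keys)]
    if (!all(unlist(modules) %in% universe)) {
      abort("modules contain genes outside the universe")
    }
    names(modules) <- vapply(modules, module_id, character(1))
  }
  structure(list(modules = modules, universe = sort(universe),
                 min_size = min_size, max_size = max_size),
            class = "gi_clustering")
}

# stable identifier: short hash of the sorted member list
module_id <- function(genes) {
  key <- paste(genes, collapse = ";")
  h <- 5381
  for (ch in utf8ToInt(key)) h <- (h * 33 + ch) %% 2^31
  sprintf("m%08x_%d", h, length(genes))
}

#' @export
print.gi_clustering <- function(x, ...) {
  cat(sprintf("<gi_clustering> %d modules (sizes %s) over %d genes; %d distinct genes in modules\n",
              length(x$modules),
              if (length(x$modules) > 0)
                paste0(min(lengths(x$modules)), "-", max(lengths(x$modules)))
              else "-",
              length(x$universe), length(module_genes(x))))
  invisible(x)
}

#' Distinct genes covered by a clustering solution
#'
#' @param s A `gi_clustering`.
#' @return Sorted character vector.
#' @export
module_genes <- function(s) {
  sort(unique(unlist(s$modules, use.names = FALSE)))
}

#' @export
tidy.gi_clustering <- function(x, ...) {
  if (length(x$modules) == 0) {
    return(tibble(module = character(), gene = character()))
  }
  tibble(
    module = rep(names(x$modules), lengths(x$modules)),
    gene = unlist(x$modules, use.names = FALSE)
  )
}

#' @export
glance.gi_clustering <- function(x, ...) {
  tibble(
    n_modules = length(x$modules),
    n_genes_in_modules = length(module_genes(x)),
    n_universe = length(x$universe),
    fraction_covered = length(module_genes(x)) / max(1L, length(x$universe)),
    genes_per_module = length(module_genes(x)) / max(1L, length(x$modules))
  )
}

#' Module size distribution plot
#'
#' @param object A `gi_clustering`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gi_clustering <- function(object, ...) {
  df <- tibble(size = lengths(object$modules))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "module size (genes)", y = "number of modules")
}

#' Write / read a clustering solution as tab-separated text
#'
#' Two columns, `module_id gene`, one row per membership.
#'
#' @param s A `gi_clustering`.
#' @param path File path.
#' @param universe Gene universe to attach on read (defaults to the genes
#'   present in the file).
#' @param min_size,max_size Size bounds to attach on read.
#' @return The clustering, invisibly (writer) or a `gi_clustering` (reader).
#' @export
write_clustering <- function(s, path) {
  write.table(tidy(s), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(s)
}

#' @rdname write_clustering
#' @export
read_clustering <- function(path, universe = NULL, min_size = 1, max_size = Inf) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  modules <- split(df$gene, df$module)
  gi_clustering(modules, universe %||% sort(unique(df$gene)),
                min_size, max_size)
}
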