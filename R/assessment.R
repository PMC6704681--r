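#' Confusion matrix between two clustering solutions
#'
#' Cell (i, j) counts the genes shared by module i of `a` and module j of
#' `b`. Modules are compared as they stand — overlapping or nested
#' modules are not deduplicated, matching the one-to-one semantics of
#' the assignment step downstream.
#'
#' @param a,b `gi_clustering` objects with at least one module each.
#' @return Integer matrix with `a`'s module ids as row names and `b`'s
#'   as column names.
#' @export
confusion_matrix <- function(a, b) {
  stopifnot(inherits(a, "gi_clustering"), inherits(b, "gi_clustering"))
  if (length(a$modules) == 0 || length(b$modules) == 0) {
    abort("both clustering solutions must contain at least one module")
  }
  m <- vapply(b$modules, function(mb) {
    vapply(a$modules, function(ma) length(intersect(ma, mb)), integer(1))
  }, integer(length(a$modules)))
  m <- matrix(m, nrow = length(a$modules),
              dimnames = list(names(a$modules), names(b$modules)))
  m
}

#' Maximum one-to-one module matching
#'
#' Total number of shared genes under the best one-to-one association of
#' rows with columns of a confusion matrix — the linear sum assignment
#' problem, solved with the Hungarian method. Rectangular matrices are
#' padded with zero rows/columns internally.
#'
#' @param M Non-negative numeric matrix (typically a [confusion_matrix()]).
#' @return The maximal total as a number.
#' @export
max_assignment <- function(M) {
  if (!is.matrix(M) || length(M) == 0) abort("`M` must be a non-empty matrix")
  if (any(M < 0)) abort("`M` must be non-negative")
  n <- max(dim(M))
  sq <- matrix(0, n, n)
  sq[seq_len(nrow(M)), seq_len(ncol(M))] <- M
  sol <- clue::solve_LSAP(sq, maximum = TRUE)
  sum(sq[cbind(seq_len(n), as.integer(sol))])
}

#' Clustering Error between two solutions
#'
#' `CE = (|U| - D) / |U|` where `U` is the set of distinct genes
#' appearing in any module of either solution and `D` is the maximal
#' total overlap under a one-to-one matching of modules
#' ([max_assignment()] of the [confusion_matrix()]). Ranges from 0 for
#' identical solutions to 1 for solutions sharing no genes.
#'
#' When modules within a solution overlap or nest, the matched total `D`
#' can exceed the number of distinct genes (each module pair is counted
#' independently); the index is clamped at 0 so that identical solutions
#' always score 0 regardless of nesting.
#'
#' @param a,b `gi_clustering` objects covering at least one gene between them.
#' @return A number in `[0, 1]`.
#' @export
clustering_error <- function(a, b) {
  u <- union(module_genes(a), module_genes(b))
  if (length(u) == 0) abort("neither solution covers any gene")
  d <- max_assignment(confusion_matrix(a, b))
  max(0, (length(u) - d) / length(u))
}

#' Annotation tables
#'
#' Annotations are held as a two-column tibble `gene`, `term` (one row
#' per gene-term assignment). A gene absent from the table, or present
#' with no terms, is *uncharacterized*. The table is flat: no term
#' hierarchy is applied, so users wanting ontology ancestors must
#' pre-propagate them.
#'
#' @param x Data frame with columns `gene` and `term`.
#' @param path Path to a two-column tab-separated file without header.
#' @return A tibble with columns `gene`, `term`.
#' @export
annotation_map <- function(x) {
  x <- as_tibble(x)
  if (!all(c("gene", "term") %in% names(x))) {
    abort("annotations need columns `gene` and `term`")
  }
  dplyr::distinct(x[, c("gene", "term")])
}

#' @rdname annotation_map
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("gene", "term"))
  annotation_map(df)
}

#' @rdname annotation_map
#' @param ann An annotation table.
#' @param genes Character vector to filter on.
#' @return `uncharacterized()`: the subset of `genes` with no annotation term.
#' @export
uncharacterized <- function(ann, genes) {
  ann <- annotation_map(ann)
  setdiff(genes, unique(ann$gene[ann$gene %in% genes]))
}

# gene -> list of terms, for pair lookups
terms_by_gene <- function(ann) {
  ann <- annotation_map(ann)
  split(ann$term, ann$gene)
}

#' Biological Homogeneity Index of one cluster
#'
#' The probability that two annotated genes drawn from the cluster share
#' at least one functional term: with `n` annotated genes, the fraction
#' of ordered pairs `x != y` for which the term sets intersect.
#' Undefined (`NA`) when fewer than two genes are annotated.
#'
#' @param cluster Character vector of genes.
#' @param ann Annotation table (see [annotation_map()]).
#' @return A number in `[0, 1]`, or `NA` if undefined.
#' @export
bhi_cluster <- function(cluster, ann) {
  tb <- terms_by_gene(ann)
  terms <- tb[intersect(cluster, names(tb))]
  n <- length(terms)
  if (n < 2) return(NA_real_)
  linked <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (length(intersect(terms[[i]], terms[[j]])) > 0) linked <- linked + 1L
    }
  }
  # ordered pairs double both the linked count and n(n-1); ratio unchanged
  2 * linked / (n * (n - 1))
}

#' Biological Homogeneity Index of a clustering solution
#'
#' Unweighted mean of the defined per-cluster [bhi_cluster()] values;
#' clusters whose score cannot be computed (fewer than two annotated
#' genes) are dropped from the average.
#'
#' @param s A `gi_clustering`.
#' @param ann Annotation table.
#' @return A number in `[0, 1]`.
#' @export
bhi_solution <- function(s, ann) {
  stopifnot(inherits(s, "gi_clustering"))
  v <- vapply(s$modules, bhi_cluster, numeric(1), ann = ann)
  v <- v[!is.na(v)]
  if (length(v) == 0) abort("no cluster has a defined homogeneity score")
  mean(v)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` when drawing `n` items without replacement from a
#' population of `N` containing `K` successes — the one-sided Fisher
#' exact probability for a 2x2 table.
#'
#' @param k Observed successes in the draw.
#' @param K Successes in the population.
#' @param n Draw size.
#' @param N Population size.
#' @return A probability.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (!(k >= 0 && K >= 0 && n >= 0 && k <= min(K, n) && max(K, n) <= N)) {
    abort("need 0 <= k <= min(K, n) <= N")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment of uncharacterized genes in a clustering solution
#'
#' Compares the proportion of uncharacterized genes among the distinct
#' genes of the solution with the proportion in the universe, using a
#' one-sided exact hypergeometric test in the direction of the observed
#' deviation (`two_sided = TRUE` doubles the smaller tail, capped at 1).
#'
#' @param s A `gi_clustering`.
#' @param ann Annotation table.
#' @param universe Character vector of genes the solution was drawn from.
#' @param two_sided Report a two-sided p-value instead.
#' @return One-row tibble: `n_genes`, `n_uncharacterized`, `proportion`,
#'   `universe_proportion`, `direction` (`"over"`/`"under"`), `p_value`,
#'   `modules_with_uncharacterized`.
#' @export
uncharacterized_enrichment <- function(s, ann, universe, two_sided = FALSE) {
  stopifnot(inherits(s, "gi_clustering"), length(universe) > 0)
  genes <- module_genes(s)
  if (!all(genes %in% universe)) abort("solution contains genes outside the universe")
  unk_universe <- uncharacterized(ann, universe)
  k <- sum(genes %in% unk_universe)
  n <- length(genes)
  K <- length(unk_universe)
  N <- length(universe)
  over <- k / n >= K / N
  p <- if (over) {
    hypergeom_upper_tail(k, K, n, N)
  } else {
    phyper(k, K, N - K, n) # P(X <= k)
  }
  if (two_sided) p <- min(1, 2 * p)
  unk_set <- unk_universe
  tibble(
    n_genes = n,
    n_uncharacterized = k,
    proportion = k / n,
    universe_proportion = K / N,
    direction = if (over) "over" else "under",
    p_value = p,
    modules_with_uncharacterized =
      sum(vapply(s$modules, function(m) any(m %in% unk_set), logical(1)))
  )
}

#' Genes shared by two clustering solutions
#'
#' Counts the distinct genes covered by both solutions and attaches the
#' hypergeometric upper-tail probability of seeing at least that overlap
#' given the two coverage sizes and the universe.
#'
#' @param a,b `gi_clustering` objects.
#' @param universe Character vector containing all genes of both solutions.
#' @return One-row tibble: `n_a`, `n_b`, `shared`, `p_value`.
#' @export
shared_gene_overlap <- function(a, b, universe) {
  ga <- module_genes(a)
  gb <- module_genes(b)
  if (!all(c(ga, gb) %in% universe)) {
    abort("solutions contain genes outside the universe")
  }
  shared <- length(intersect(ga, gb))
  tibble(
    n_a = length(ga), n_b = length(gb), shared = shared,
    p_value = hypergeom_upper_tail(shared, length(ga), length(gb), length(universe))
  )
}

#' Consistency of one module against a reference clustering
#'
#' A module is consistent when (i) at least 80% of its genes fall into a
#' single reference cluster, and (ii) the largest fraction of its genes
#' sharing one common annotation term reaches 80% for modules of 10 or
#' more genes, or 50% for smaller modules.
#'
#' @param m Character vector: the module's genes.
#' @param reference A `gi_clustering` used as the reference assignment.
#' @param ann Annotation table.
#' @return One-row tibble: `consistent` plus the two observed fractions.
#' @export
module_consistency <- function(m, reference, ann) {
  stopifnot(length(m) > 0, inherits(reference, "gi_clustering"))
  in_ref <- vapply(reference$modules, function(rc) sum(m %in% rc), integer(1))
  ref_frac <- if (length(in_ref) > 0) max(in_ref) / length(m) else 0
  ann <- annotation_map(ann)
  ann_sub <- ann[ann$gene %in% m, , drop = FALSE]
  term_frac <- if (nrow(ann_sub) > 0) {
    max(table(ann_sub$term)) / length(m)
  } else 0
  need <- if (length(m) >= 10) 0.8 else 0.5
  tibble(
    consistent = ref_frac >= 0.8 && term_frac >= need,
    reference_fraction = ref_frac,
    annotation_fraction = term_frac
  )
}

#' Share of genes already known to be functionally linked
#'
#' An annotation-based proxy for labelling small modules: a module is
#' labelled type 1 when more than half of its genes share one common
#' annotation term, type 2 otherwise.
#'
#' @param m Character vector: the module's genes.
#' @param ann Annotation table.
#' @return `"type1"` or `"type2"`.
#' @export
module_type <- function(m, ann) {
  ann <- annotation_map(ann)
  ann_sub <- ann[ann$gene %in% m, , drop = FALSE]
  frac <- if (nrow(ann_sub) > 0) max(table(ann_sub$term)) / length(m) else 0
  if (frac > 0.5) "type1" else "type2"
}
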