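#' All-pairs profile similarity from a score supermatrix (one-square route)
#'
#' Computes the similarity between every pair of gene profiles, i.e. rows
#' of the symmetric score supermatrix. For the binary coefficients the
#' supermatrix is binarized first (strict `> threshold`); for
#' `"pearson"` the raw real-valued rows are used directly.
#'
#' @param R A `gi_supermatrix` from [build_one_square()].
#' @param measure One of [similarity_measures()].
#' @param threshold Binarization threshold passed to [binarize()]
#'   (ignored for `"pearson"`).
#' @return A `gi_similarity`: list with `values` (symmetric numeric
#'   matrix), `defined` (symmetric logical mask), `gene_ids`, `measure`
#'   and `transformation`. The diagonal is excluded from summaries and
#'   never becomes a network edge.
#' @export
similarity_one_square <- function(R, measure, threshold = 0.5) {
  stopifnot(inherits(R, "gi_supermatrix"))
  measure <- match.arg(measure, similarity_measures())
  prof <- if (measure == "pearson") R$values else binarize(R, threshold)$bits
  ps <- pairwise_row_similarity(prof, measure)
  new_gi_similarity(ps$values, ps$defined, R$gene_ids, measure, "one_square")
}

#' All-pairs profile similarity from the raw screen (two-squares route)
#'
#' Computes a query x query similarity matrix `Q` from the rows of the
#' raw screen matrix and an array x array matrix `A` from its columns,
#' then merges both into a symmetric gene x gene matrix over the full
#' gene universe: entries present in both `Q` and `A` are averaged,
#' entries present in neither (one gene query-only, the other
#' array-only) are undefined.
#'
#' @param m A [gi_matrix()].
#' @inheritParams similarity_one_square
#' @return A `gi_similarity` with `transformation = "two_squares"`.
#' @export
similarity_two_squares <- function(m, measure, threshold = 0.5) {
  stopifnot(inherits(m, "gi_matrix"))
  measure <- match.arg(measure, similarity_measures())
  genes <- gene_universe(m)
  n <- length(genes)
  x <- m$scores
  x[is.na(x)] <- 0
  if (measure != "pearson") x <- (x > threshold) * 1L

  q_sim <- pairwise_row_similarity(x, measure)
  a_sim <- pairwise_row_similarity(t(x), measure)

  sum_v <- matrix(0, n, n, dimnames = list(genes, genes))
  cnt <- matrix(0L, n, n, dimnames = list(genes, genes))
  place <- function(block, ids) {
    ix <- match(ids, genes)
    def <- block$defined
    v <- block$values
    v[!def] <- 0
    sum_v[ix, ix] <<- sum_v[ix, ix] + v
    cnt[ix, ix] <<- cnt[ix, ix] + (def * 1L)
  }
  place(q_sim, query_ids(m))
  place(a_sim, array_ids(m))

  defined <- cnt > 0L
  values <- matrix(0, n, n, dimnames = list(genes, genes))
  values[defined] <- sum_v[defined] / cnt[defined]
  new_gi_similarity(values, defined, genes, measure, "two_squares")
}

new_gi_similarity <- function(values, defined, gene_ids, measure, transformation) {
  dimnames(values) <- list(gene_ids, gene_ids)
  dimnames(defined) <- dimnames(values)
  structure(
    list(values = values, defined = defined, gene_ids = gene_ids,
         measure = measure, transformation = transformation),
    class = "gi_similarity"
  )
}

#' @export
print.gi_similarity <- function(x, ...) {
  ut <- upper.tri(x$values)
  cat(sprintf("<gi_similarity> %s / %s: %d genes, %d defined pairs\n",
              x$measure, x$transformation, length(x$gene_ids),
              sum(x$defined[ut])))
  invisible(x)
}

#' Summary statistics of a similarity matrix
#'
#' Mean, population variance, median, minimum and maximum over the
#' defined, off-diagonal, upper-triangle entries — the statistics used
#' to characterize the similarity distribution of a screen. Self
#' similarities are excluded so they cannot inflate the summaries.
#'
#' @param S A `gi_similarity`.
#' @return One-row tibble with columns `measure`, `transformation`,
#'   `n_pairs`, `mean`, `variance`, `median`, `minimum`, `maximum`.
#' @export
similarity_summary <- function(S) {
  stopifnot(inherits(S, "gi_similarity"))
  ut <- upper.tri(S$values)
  v <- S$values[ut & S$defined]
  if (length(v) == 0) abort("similarity matrix has no defined off-diagonal entries")
  tibble(
    measure = S$measure,
    transformation = S$transformation,
    n_pairs = length(v),
    mean = mean(v),
    variance = mean((v - mean(v))^2),
    median = median(v),
    minimum = min(v),
    maximum = max(v)
  )
}

#' @export
glance.gi_similarity <- function(x, ...) similarity_summary(x)

#' @export
tidy.gi_similarity <- function(x, ...) {
  ut <- upper.tri(x$values)
  keep <- ut & x$defined
  idx <- which(keep, arr.ind = TRUE)
  tibble(
    gene_a = x$gene_ids[idx[, 1]],
    gene_b = x$gene_ids[idx[, 2]],
    similarity = x$values[keep]
  ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Cumulative similarity distribution plot
#'
#' Empirical cumulative distribution of the defined off-diagonal
#' similarities, the standard way to compare how heavy-tailed different
#' measures are on the same screen.
#'
#' @param object A `gi_similarity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gi_similarity <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$similarity)) +
    ggplot2::stat_ecdf(pad = FALSE) +
    ggplot2::labs(
      x = sprintf("similarity (%s, %s)", object$measure, object$transformation),
      y = "cumulative fraction of gene pairs"
    )
}

#' Write / read a similarity matrix as tab-separated text
#'
#' The matrix is written as a gene x gene table (same dialect as the
#' input screens; undefined entries as empty cells) plus a sidecar
#' `<path>.meta` file recording measure and transformation.
#'
#' @param S A `gi_similarity`.
#' @param path Output path.
#' @return `S` (writer, invisibly) or a `gi_similarity` (reader).
#' @export
write_similarity_matrix <- function(S, path) {
  v <- S$values
  v[!S$defined] <- NA
  write_interaction_matrix(gi_matrix(v), path)
  writeLines(c(paste0("measure\t", S$measure),
               paste0("transformation\t", S$transformation)),
             paste0(path, ".meta"))
  invisible(S)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  m <- read_interaction_matrix(path)
  meta <- read.delim(paste0(path, ".meta"), header = FALSE, row.names = 1)
  v <- m$scores
  defined <- !is.na(v)
  v[!defined] <- 0
  new_gi_similarity(v, defined, rownames(v),
                    meta["measure", 1], meta["transformation", 1])
}
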