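#' Construct a query x array interaction matrix
#'
#' An interaction matrix holds the raw double-mutant scores of a genetic
#' interaction screen: one row per query gene, one column per array gene.
#' Cells that were never measured are `NA`. A gene screened under several
#' conditions must arrive with distinct, pre-suffixed labels (for example
#' `"GENE__27C"`); labels are never merged.
#'
#' @param scores Numeric matrix with unique, non-empty row names (query gene
#'   labels) and column names (array gene labels). `NA` marks an unmeasured
#'   cell.
#' @return An object of class `gi_matrix`.
#' @examples
#' x <- matrix(c(0.6, NA, 0.2, 0.8, 0.1, -0.3), nrow = 2,
#'             dimnames = list(c("geneA", "geneB"), c("geneB", "geneC", "geneD")))
#' gi_matrix(x)
#' @export
gi_matrix <- function(scores) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    abort("`scores` must be a numeric matrix.")
  }
  qn <- rownames(scores)
  an <- colnames(scores)
  if (is.null(qn) || is.null(an) || any(qn == "") || any(an == "")) {
    abort("`scores` must have non-empty row and column names (gene labels).")
  }
  dup_q <- qn[duplicated(qn)]
  if (length(dup_q) > 0) {
    abort(paste0("duplicate query gene label(s): ", paste(unique(dup_q), collapse = ", ")))
  }
  dup_a <- an[duplicated(an)]
  if (length(dup_a) > 0) {
    abort(paste0("duplicate array gene label(s): ", paste(unique(dup_a), collapse = ", ")))
  }
  structure(list(scores = scores), class = "gi_matrix")
}

#' @export
print.gi_matrix <- function(x, ...) {
  sc <- x$scores
  cat(sprintf("<gi_matrix> %d query x %d array genes, %d measured scores\n",
              nrow(sc), ncol(sc), sum(!is.na(sc))))
  invisible(x)
}

#' Query and array gene labels
#'
#' @param m A [gi_matrix()].
#' @return Character vector of labels, in matrix order.
#' @export
query_ids <- function(m) rownames(m$scores)

#' @rdname query_ids
#' @export
array_ids <- function(m) colnames(m$scores)

#' Read an interaction matrix from a tab-separated file
#'
#' Expects the DRYGIN-style layout: first row holds the array gene labels,
#' first column the query gene labels, remaining cells are numeric scores.
#' Empty cells are unmeasured (`NA`). With `zero_is_unmeasured = TRUE` a
#' literal 0 is also treated as unmeasured, for deposits that encode
#' untested pairs as zeros.
#'
#' @param path Path to a tab-separated file.
#' @param zero_is_unmeasured Treat exact zeros as unmeasured cells.
#' @return A [gi_matrix()].
#' @export
read_interaction_matrix <- function(path, zero_is_unmeasured = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) abort("file must contain a header row and at least one query row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  arr <- header[-1]
  n_col <- length(arr)
  body <- fields[-1]
  qry <- character(length(body))
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_col)
  for (i in seq_along(body)) {
    row <- body[[i]]
    # trailing empty fields are dropped by strsplit; pad them back
    if (length(row) < n_col + 1) row <- c(row, rep("", n_col + 1 - length(row)))
    if (length(row) != n_col + 1) {
      abort(sprintf("ragged row %d: expected %d fields, found %d", i, n_col + 1, length(row)))
    }
    qry[i] <- row[1]
    cell <- row[-1]
    filled <- nzchar(trimws(cell))
    v <- rep(NA_real_, n_col)
    v[filled] <- as.numeric(cell[filled])
    vals[i, ] <- v
  }
  if (zero_is_unmeasured) vals[!is.na(vals) & vals == 0] <- NA_real_
  dimnames(vals) <- list(qry, arr)
  gi_matrix(vals)
}

#' Write an interaction matrix to a tab-separated file
#'
#' Inverse of [read_interaction_matrix()]: unmeasured cells become empty
#' fields, labels are written verbatim.
#'
#' @param m A [gi_matrix()].
#' @param path Output file path.
#' @return `m`, invisibly.
#' @export
write_interaction_matrix <- function(m, path) {
  sc <- m$scores
  chr <- matrix("", nrow = nrow(sc), ncol = ncol(sc))
  meas <- !is.na(sc)
  chr[meas] <- format(sc[meas], digits = 15, trim = TRUE, scientific = FALSE)
  lines <- c(
    paste(c("", colnames(sc)), collapse = "\t"),
    vapply(seq_len(nrow(sc)), function(i) {
      paste(c(rownames(sc)[i], chr[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(m)
}

#' Gene universe of a screen
#'
#' The lexicographically sorted union of query and array gene labels, with
#' no duplicates. All symmetric gene x gene matrices built by this package
#' are indexed in this canonical order.
#'
#' @param m A [gi_matrix()].
#' @return Character vector of gene labels.
#' @export
gene_universe <- function(m) {
  sort(unique(c(query_ids(m), array_ids(m))))
}

#' Build the symmetric score supermatrix ("one square" transformation)
#'
#' Places every measured score of the query x array matrix into a symmetric
#' gene x gene supermatrix over the full gene universe. When both the
#' (i, j) and (j, i) crosses were measured (genes present on both axes),
#' the two reciprocal scores are averaged. Pairs never tested are set to 0
#' and flagged unmeasured in the mask; the diagonal is always unmeasured
#' (a screen never crosses a gene with itself).
#'
#' @param m A [gi_matrix()].
#' @return A `gi_supermatrix`: list with `values` (symmetric numeric
#'   matrix, zeros where unmeasured), `measured` (symmetric logical mask)
#'   and `gene_ids`.
#' @export
build_one_square <- function(m) {
  genes <- gene_universe(m)
  n <- length(genes)
  sc <- m$scores
  qi <- match(rownames(sc), genes)
  ai <- match(colnames(sc), genes)

  sum_m <- matrix(0, n, n, dimnames = list(genes, genes))
  cnt_m <- matrix(0L, n, n, dimnames = list(genes, genes))
  meas <- !is.na(sc)
  idx <- which(meas, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    ri <- qi[idx[, 1]]
    ci <- ai[idx[, 2]]
    v <- sc[meas]
    # each query x array cell maps to a distinct (ri, ci); adding the
    # transpose below makes reciprocal measurements average
    sum_m[cbind(ri, ci)] <- v
    cnt_m[cbind(ri, ci)] <- 1L
  }
  tot <- sum_m + t(sum_m)
  cnt <- cnt_m + t(cnt_m)
  diag(tot) <- 0
  diag(cnt) <- 0L
  values <- matrix(0, n, n, dimnames = list(genes, genes))
  measured <- cnt > 0L
  values[measured] <- tot[measured] / cnt[measured]
  structure(list(values = values, measured = measured, gene_ids = genes),
            class = "gi_supermatrix")
}

#' @export
print.gi_supermatrix <- function(x, ...) {
  n <- length(x$gene_ids)
  cat(sprintf("<gi_supermatrix> %d genes, %d measured pairs\n",
              n, sum(x$measured[upper.tri(x$measured)])))
  invisible(x)
}

#' Binarize a score supermatrix
#'
#' Scores strictly greater than `threshold` become 1, everything else
#' (including unmeasured entries, stored as 0) becomes 0. The default
#' threshold of 0.5 is the conventional cut for calling a strong
#' interaction on these score scales.
#'
#' @param S A `gi_supermatrix` from [build_one_square()].
#' @param threshold Finite numeric scalar; a score exactly equal to the
#'   threshold maps to 0.
#' @return A `gi_binary`: list with `bits` (symmetric 0/1 integer matrix)
#'   and `gene_ids`.
#' @export
binarize <- function(S, threshold = 0.5) {
  stopifnot(inherits(S, "gi_supermatrix"), is.numeric(threshold),
            length(threshold) == 1, is.finite(threshold))
  bits <- (S$values > threshold) * 1L
  storage.mode(bits) <- "integer"
  dimnames(bits) <- dimnames(S$values)
  structure(list(bits = bits, gene_ids = S$gene_ids), class = "gi_binary")
}

#' @export
print.gi_binary <- function(x, ...) {
  cat(sprintf("<gi_binary> %d genes, %d positive pairs\n",
              length(x$gene_ids), sum(x$bits[upper.tri(x$bits)])))
  invisible(x)
}

#' @export
tidy.gi_matrix <- function(x, ...) {
  sc <- x$scores
  out <- tibble(
    query = rep(rownames(sc), times = ncol(sc)),
    array = rep(colnames(sc), each = nrow(sc)),
    score = as.vector(sc)
  )
  dplyr::filter(out, !is.na(.data$score))
}

#' @export
glance.gi_matrix <- function(x, ...) {
  sc <- x$scores
  tibble(
    n_query = nrow(sc), n_array = ncol(sc),
    n_genes = length(gene_universe(x)),
    n_measured = sum(!is.na(sc)),
    fraction_measured = mean(!is.na(sc))
  )
}
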