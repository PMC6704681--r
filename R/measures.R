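#' Similarity coefficients between interaction profiles
#'
#' Scalar similarity coefficients between two profiles of equal length.
#' The binary coefficients are defined through `a`, the number of
#' positions where both vectors carry a 1, and `|x|`, `|y|`, the numbers
#' of 1s in each vector:
#'
#' * Maryland bridge: `(a/|x| + a/|y|) / 2`
#' * Ochiai: `a / sqrt(|x| * |y|)`
#' * Braun-Blanquet: `a / max(|x|, |y|)` (variant `"max"`, the classical
#'   form) or `a / min(|x|, |y|)` (variant `"min"`)
#' * Dice (Sorensen-Dice): `2a / (|x| + |y|)`, the harmonic mean of the
#'   two Braun-Blanquet coefficients
#' * Jaccard: `a / (|x| + |y| - a)`
#'
#' Whenever a denominator would be zero (a profile with no 1s), the
#' similarity is defined as 0: a gene with no interactions above
#' threshold shares none. `pearson_similarity()` is the product-moment
#' correlation of the raw (real-valued) profiles and is defined as 0 when
#' either profile has zero variance.
#'
#' @param x,y Equal-length numeric vectors; 0/1 for the binary
#'   coefficients, real-valued for `pearson_similarity()`.
#' @param variant For `braun_blanquet()`: normalize by the larger
#'   (`"max"`) or smaller (`"min"`) support.
#' @return A similarity in `[0, 1]` (binary coefficients) or `[-1, 1]`
#'   (Pearson).
#' @examples
#' x <- c(1, 1, 0, 0); y <- c(1, 0, 1, 0)   # share half of their 1s
#' maryland_bridge(x, y)   # 0.5
#' dice(x, y)              # 0.5
#' jaccard(x, y)           # 1/3
#' @name similarity_coefficients
NULL

check_pair <- function(x, y) {
  if (length(x) != length(y)) {
    abort(sprintf("profiles have different lengths (%d vs %d)", length(x), length(y)))
  }
}

#' @rdname similarity_coefficients
#' @export
maryland_bridge <- function(x, y) {
  check_pair(x, y)
  a <- sum(x * y); nx <- sum(x); ny <- sum(y)
  if (nx == 0 || ny == 0) return(0)
  (a / nx + a / ny) / 2
}

#' @rdname similarity_coefficients
#' @export
ochiai <- function(x, y) {
  check_pair(x, y)
  a <- sum(x * y); nx <- sum(x); ny <- sum(y)
  if (nx == 0 || ny == 0) return(0)
  a / sqrt(nx * ny)
}

#' @rdname similarity_coefficients
#' @export
braun_blanquet <- function(x, y, variant = c("max", "min")) {
  variant <- match.arg(variant)
  check_pair(x, y)
  a <- sum(x * y); nx <- sum(x); ny <- sum(y)
  d <- if (variant == "max") max(nx, ny) else min(nx, ny)
  if (d == 0) return(0)
  a / d
}

#' @rdname similarity_coefficients
#' @export
dice <- function(x, y) {
  check_pair(x, y)
  a <- sum(x * y); s <- sum(x) + sum(y)
  if (s == 0) return(0)
  2 * a / s
}

#' @rdname similarity_coefficients
#' @export
jaccard <- function(x, y) {
  check_pair(x, y)
  a <- sum(x * y); u <- sum(x) + sum(y) - a
  if (u == 0) return(0)
  a / u
}

#' @rdname similarity_coefficients
#' @export
pearson_similarity <- function(x, y) {
  check_pair(x, y)
  if (length(x) < 2) abort("pearson requires profiles of length >= 2")
  sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0) return(0)
  sum((x - mean(x)) * (y - mean(y))) / sqrt(sx * sy)
}

#' Similarity measures known to the pipeline
#'
#' @return Character vector of measure labels accepted wherever a
#'   `measure` argument appears.
#' @export
similarity_measures <- function() {
  c("maryland_bridge", "ochiai", "braun_blanquet_max", "braun_blanquet_min",
    "dice", "jaccard", "pearson")
}

measure_fun <- function(measure) {
  switch(measure,
    maryland_bridge = maryland_bridge,
    ochiai = ochiai,
    braun_blanquet_max = function(x, y) braun_blanquet(x, y, "max"),
    braun_blanquet_min = function(x, y) braun_blanquet(x, y, "min"),
    dice = dice,
    jaccard = jaccard,
    pearson = pearson_similarity,
    abort(sprintf("unknown similarity measure '%s'", measure))
  )
}

# All-pairs similarity of the rows of a profile matrix, vectorized.
# For binary measures `m` is a 0/1 matrix; for pearson, real-valued.
# Returns list(values, defined): rows with empty support (binary) or
# zero variance (pearson) give similarity 0, flagged defined = FALSE.
pairwise_row_similarity <- function(m, measure) {
  n <- nrow(m)
  if (measure == "pearson") {
    sds <- apply(m, 1, function(r) sum((r - mean(r))^2))
    ok <- sds > 0
    values <- matrix(0, n, n)
    if (any(ok)) {
      values[ok, ok] <- cor(t(m[ok, , drop = FALSE]))
    }
    defined <- outer(ok, ok, "&")
  } else {
    a <- tcrossprod(m)            # shared 1s
    s <- rowSums(m)               # supports
    ok <- s > 0
    zero_safe <- ifelse(ok, s, 1)
    values <- switch(measure,
      maryland_bridge = (a / zero_safe + t(a / zero_safe)) / 2,
      ochiai = a / sqrt(outer(zero_safe, zero_safe)),
      braun_blanquet_max = a / outer(s, s, pmax),
      braun_blanquet_min = {
        mn <- outer(zero_safe, zero_safe, pmin)
        a / mn
      },
      dice = 2 * a / outer(s, s, "+"),
      jaccard = a / (outer(s, s, "+") - a),
      abort(sprintf("unknown similarity measure '%s'", measure))
    )
    values[!is.finite(values)] <- 0
    values[!ok, ] <- 0
    values[, !ok] <- 0
    # zero-support rows are still "defined" as 0 by convention
    defined <- matrix(TRUE, n, n)
  }
  dimnames(values) <- list(rownames(m), rownames(m))
  dimnames(defined) <- dimnames(values)
  list(values = (values + t(values)) / 2, defined = defined & t(defined))
}
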