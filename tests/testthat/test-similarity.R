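test_that("coefficients reproduce their closed-form values on hand examples", {
  x <- c(1, 1, 0, 0); y <- c(1, 0, 1, 0)   # equal supports, half shared
  expect_equal(maryland_bridge(x, y), 0.5)
  expect_equal(dice(x, y), 0.5)
  expect_equal(jaccard(x, y), 1 / 3)

  a <- c(1, 1, 1, 0); b <- c(1, 0, 0, 0)   # nested supports of sizes 3 and 1
  expect_equal(maryland_bridge(a, b), (1 / 3 + 1) / 2)
  expect_equal(ochiai(a, b), 1 / sqrt(3))
  expect_equal(braun_blanquet(a, b, "max"), 1 / 3)
  expect_equal(braun_blanquet(a, b, "min"), 1)
  expect_equal(dice(a, b), 0.5)

  ident <- c(1, 0, 1, 1)
  for (f in list(maryland_bridge, ochiai, dice, jaccard,
                 function(p, q) braun_blanquet(p, q, "max"),
                 function(p, q) braun_blanquet(p, q, "min"))) {
    expect_equal(f(ident, ident), 1)
    expect_equal(f(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)  # disjoint supports
    expect_equal(f(ident, rep(0, 4)), 0)              # empty support convention
  }

  expect_equal(pearson_similarity(1:3, 1:3), 1)
  expect_equal(pearson_similarity(1:3, 3:1), -1)
  expect_equal(pearson_similarity(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0)
  expect_equal(pearson_similarity(c(2, 2, 2), c(1, 2, 3)), 0)  # constant profile

  expect_error(maryland_bridge(c(1, 0), c(1, 0, 1)), "length")
  expect_error(pearson_similarity(c(1, 0), c(1, 0, 1)), "length")
})

test_that("coefficient identities and the measure ordering hold over random binary pairs", {
  withr::local_seed(2024)
  n_pairs <- 10000
  len <- 40
  checked <- 0
  bad <- character()
  note <- function(cond, what) if (!cond) bad <<- c(bad, what)
  for (i in seq_len(n_pairs)) {
    x <- rbinom(len, 1, runif(1, 0.05, 0.6))
    y <- rbinom(len, 1, runif(1, 0.05, 0.6))
    if (sum(x) == 0 || sum(y) == 0) next
    checked <- checked + 1
    bmax <- braun_blanquet(x, y, "max")
    bmin <- braun_blanquet(x, y, "min")
    d <- dice(x, y); o <- ochiai(x, y); mb <- maryland_bridge(x, y)
    j <- jaccard(x, y)
    # ordering: BBmax <= Dice <= Ochiai <= Mb <= BBmin
    note(bmax <= d + 1e-12 && d <= o + 1e-12 &&
         o <= mb + 1e-12 && mb <= bmin + 1e-12, "ordering")
    # Ochiai is the geometric, Dice the harmonic mean of the BB pair
    note(abs(o^2 - bmax * bmin) < 1e-12, "geometric mean")
    note(bmax + bmin == 0 ||
         abs(d - 2 * bmax * bmin / (bmax + bmin)) < 1e-12, "harmonic mean")
    note(all(c(bmax, bmin, d, o, mb, j) >= 0 & c(bmax, bmin, d, o, mb, j) <= 1),
         "range")
    note(mb == maryland_bridge(y, x) && o == ochiai(y, x), "symmetry")
    # phi-coefficient identity for pearson on 0/1 data
    n11 <- sum(x & y); n10 <- sum(x & !y); n01 <- sum(!x & y); n00 <- sum(!x & !y)
    denom <- sqrt((n11 + n10) * (n01 + n00) * (n11 + n01) * (n10 + n00))
    note(denom == 0 ||
         abs(pearson_similarity(x, y) - (n11 * n00 - n10 * n01) / denom) < 1e-12,
         "phi")
  }
  expect_gt(checked, 9000)
  expect_equal(unique(bad), character())
})

test_that("one-square all-pairs matrices match the scalar-loop oracle for every measure", {
  withr::local_seed(7)
  genes <- sprintf("g%02d", 1:20)
  v <- matrix(rnorm(400, 0.3, 0.4), 20, dimnames = list(genes, genes))
  v <- (v + t(v)) / 2
  diag(v) <- NA
  R <- build_one_square(gi_matrix(v))
  B <- binarize(R)$bits
  scalar <- list(
    maryland_bridge = maryland_bridge,
    ochiai = ochiai,
    braun_blanquet_max = function(x, y) braun_blanquet(x, y, "max"),
    braun_blanquet_min = function(x, y) braun_blanquet(x, y, "min"),
    dice = dice,
    jaccard = jaccard,
    pearson = pearson_similarity
  )
  for (ms in names(scalar)) {
    S <- similarity_one_square(R, ms)
    prof <- if (ms == "pearson") R$values else B
    expect_equal(unname(S$values), unname(loop_similarity_matrix(prof, scalar[[ms]])),
                 tolerance = 1e-12, info = ms)
    expect_identical(S$values, t(S$values))
  }
  expect_error(similarity_one_square(R, "cosine"))
})

test_that("two-squares merging averages shared entries and leaves unmatched pairs undefined", {
  # disjoint axes: cross pairs undefined, Q and A blocks kept as-is
  x <- matrix(c(0.9, 0.7, 0.6, 0.8), 2,
              dimnames = list(c("A", "B"), c("C", "D")))
  S <- similarity_two_squares(gi_matrix(x), "pearson")
  expect_false(S$defined["A", "C"])
  expect_false(S$defined["B", "D"])
  expect_true(S$defined["A", "B"])
  expect_true(S$defined["C", "D"])

  # symmetric square screen: Q == A so the average equals Q
  genes <- sprintf("g%d", 1:5)
  withr::local_seed(3)
  y <- matrix(rnorm(25), 5, dimnames = list(genes, genes))
  y <- (y + t(y)) / 2
  Sq <- similarity_two_squares(gi_matrix(y), "ochiai")
  q_only <- loop_similarity_matrix(1 * (y > 0.5), ochiai)
  expect_equal(unname(Sq$values), unname(q_only), tolerance = 1e-12)

  # rectangular screen with overlap: every defined entry matches a
  # hand-looped oracle that builds Q and A separately, then averages
  qn <- sprintf("g%d", 1:6); an <- sprintf("g%d", 3:10)
  z <- matrix(rnorm(48), 6, 8, dimnames = list(qn, an))
  S2 <- similarity_two_squares(gi_matrix(z), "pearson")
  q_m <- loop_similarity_matrix(z, pearson_similarity)
  a_m <- loop_similarity_matrix(t(z), pearson_similarity)
  for (g1 in S2$gene_ids) {
    for (g2 in S2$gene_ids) {
      vals <- c(
        if (g1 %in% qn && g2 %in% qn) q_m[g1, g2],
        if (g1 %in% an && g2 %in% an) a_m[g1, g2]
      )
      if (length(vals) == 0) {
        expect_false(S2$defined[g1, g2])
      } else {
        expect_true(S2$defined[g1, g2])
        expect_equal(S2$values[g1, g2], mean(vals), tolerance = 1e-12)
      }
    }
  }
})

test_that("similarity summaries use defined off-diagonal entries only", {
  vals <- matrix(c(1, 0.2, 0.4, 0.2, 1, NA, 0.4, NA, 1), 3,
                 dimnames = list(letters[1:3], letters[1:3]))
  S <- structure(list(values = ifelse(is.na(vals), 0, vals),
                      defined = !is.na(vals), gene_ids = letters[1:3],
                      measure = "ochiai", transformation = "one_square"),
                 class = "gi_similarity")
  sm <- similarity_summary(S)
  expect_equal(sm$mean, 0.3)
  expect_equal(sm$median, 0.3)
  expect_equal(sm$minimum, 0.2)
  expect_equal(sm$maximum, 0.4)
  expect_equal(sm$variance, 0.01)   # population variance
  expect_equal(sm$n_pairs, 2)

  # agreement with a flattened-list reference on a random matrix
  withr::local_seed(12)
  genes <- sprintf("g%02d", 1:30)
  v <- matrix(rnorm(900, 0.3, 0.4), 30, dimnames = list(genes, genes))
  v <- (v + t(v)) / 2
  diag(v) <- NA
  S2 <- similarity_one_square(build_one_square(gi_matrix(v)), "maryland_bridge")
  ref <- S2$values[upper.tri(S2$values)]
  sm2 <- similarity_summary(S2)
  expect_equal(sm2$mean, mean(ref))
  expect_equal(sm2$variance, mean((ref - mean(ref))^2))
  expect_equal(sm2$median, median(ref))
})

test_that("similarity matrices survive a text round-trip with metadata", {
  withr::local_seed(8)
  genes <- sprintf("g%d", 1:6)
  v <- matrix(rnorm(36, 0.4, 0.3), 6, dimnames = list(genes, genes))
  v <- (v + t(v)) / 2
  diag(v) <- NA
  S <- similarity_one_square(build_one_square(gi_matrix(v)), "dice")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_matrix(S, path)
  back <- read_similarity_matrix(path)
  expect_equal(back$values, S$values, tolerance = 1e-12)
  expect_equal(back$measure, "dice")
  expect_equal(back$transformation, "one_square")
})
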