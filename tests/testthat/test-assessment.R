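sol <- function(..., universe = NULL) {
  mods <- list(...)
  gi_clustering(mods, universe %||% sort(unique(unlist(mods))),
                min_size = 1, max_size = 100)
}

test_that("confusion matrices count shared genes per module pair", {
  a <- sol(c("p", "q", "r"))
  b <- sol(c("p", "q"), c("r", "s"))
  expect_equal(unname(confusion_matrix(a, b)), matrix(c(2L, 1L), 1))

  s <- sol(c("a", "b"), c("c", "d", "e"))
  cm <- confusion_matrix(s, s)
  expect_equal(unname(diag(cm)), c(2L, 3L))

  d1 <- sol(c("a", "b"), universe = letters[1:10])
  d2 <- sol(c("x", "y"), universe = c("x", "y", "z"))
  expect_true(all(confusion_matrix(d1, d2) == 0))
})

test_that("the optimal assignment equals brute-force permutation search", {
  expect_equal(max_assignment(matrix(c(2, 1), 1)), 2)
  expect_equal(max_assignment(matrix(c(1, 2, 2, 1), 2)), 4)
  withr::local_seed(19)
  for (rep in 1:8) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    M <- matrix(sample(0:9, nr * nc, replace = TRUE), nr, nc)
    expect_equal(max_assignment(M), brute_max_assignment(M))
  }
})

test_that("clustering error behaves as an overlap distance", {
  a <- sol(c("w", "x", "y", "z"))
  b <- sol(c("w", "x"), c("y", "z"))
  expect_equal(clustering_error(a, b), 0.5)
  expect_equal(clustering_error(b, a), 0.5)
  expect_equal(clustering_error(a, a), 0)

  d1 <- sol(c("a", "b", "c"))
  d2 <- sol(c("x", "y"))
  expect_equal(clustering_error(d1, d2), 1)

  withr::local_seed(4)
  genes <- sprintf("g%02d", 1:30)
  for (rep in 1:5) {
    mods <- lapply(1:4, function(i) sample(genes, sample(3:8, 1)))
    s <- do.call(sol, mods)
    expect_equal(clustering_error(s, s), 0)
    other <- do.call(sol, lapply(1:3, function(i) sample(genes, 5)))
    ce <- clustering_error(s, other)
    expect_equal(ce, clustering_error(other, s))
    expect_true(ce >= 0 && ce <= 1)
  }
})

test_that("cluster homogeneity follows the annotated-pair definition", {
  ann <- annotation_map(tibble::tibble(
    gene = c("x", "y", "z", "u"),
    term = c("t1", "t1", "t2", "t1")
  ))
  expect_equal(bhi_cluster(c("x", "y", "u"), ann), 1)
  expect_equal(bhi_cluster(c("x", "y", "z"), ann), 1 / 3)  # one linked of three pairs
  expect_true(is.na(bhi_cluster(c("x", "nope"), ann)))     # one annotated gene

  s <- gi_clustering(list(c("x", "y"), c("x", "z")), letters_universe <- c("x", "y", "z", "u", "q"),
                     min_size = 1, max_size = 10)
  expect_equal(bhi_solution(s, ann), mean(c(1, 0)))
  s2 <- gi_clustering(list(c("x", "z"), c("x", "q")), letters_universe,
                      min_size = 1, max_size = 10)
  expect_equal(bhi_solution(s2, ann), 0)  # undefined cluster dropped from the mean

  # a fully homogeneous solution scores 1
  ann3 <- annotation_map(tibble::tibble(gene = c("a", "b", "c", "d"), term = "t"))
  s3 <- gi_clustering(list(c("a", "b"), c("c", "d")), c("a", "b", "c", "d"),
                      min_size = 1, max_size = 10)
  expect_equal(bhi_solution(s3, ann3), 1)
})

test_that("hypergeometric upper tails match hand enumeration and are monotone", {
  expect_equal(hypergeom_upper_tail(0, 4, 4, 8), 1)
  # N=8, K=4, n=4, k=3: (C(4,3)C(4,1) + C(4,4)C(4,0)) / C(8,4) = 17/70
  hand <- (choose(4, 3) * choose(4, 1) + choose(4, 4) * choose(4, 0)) / choose(8, 4)
  expect_equal(hypergeom_upper_tail(3, 4, 4, 8), hand)
  expect_equal(hand, 17 / 70)
  expect_equal(hypergeom_upper_tail(3, 3, 3, 3), 1)
  prev <- 1
  for (k in 0:4) {
    cur <- hypergeom_upper_tail(k, 4, 4, 8)
    expect_true(cur <= prev + 1e-14)
    prev <- cur
  }
  expect_error(hypergeom_upper_tail(5, 4, 4, 8), "need")
})

test_that("uncharacterized-gene enrichment reports the observed direction", {
  universe <- sprintf("g%d", 1:8)
  ann <- annotation_map(tibble::tibble(gene = sprintf("g%d", 1:4), term = "t"))
  # solution covers 4 genes, 3 uncharacterized, universe rate 1/2
  s <- sol(c("g5", "g6", "g7", "g1"), universe = universe)
  enr <- uncharacterized_enrichment(s, ann, universe)
  expect_equal(enr$direction, "over")
  expect_equal(enr$p_value, 17 / 70)
  expect_equal(enr$proportion, 0.75)
  expect_equal(enr$modules_with_uncharacterized, 1)

  s2 <- sol(c("g1", "g2", "g3"), universe = universe)
  expect_equal(uncharacterized_enrichment(s2, ann, universe)$direction, "under")

  s3 <- sol(universe, universe = universe)
  enr3 <- uncharacterized_enrichment(s3, ann, universe)
  expect_equal(enr3$proportion, enr3$universe_proportion)
})

test_that("shared-gene overlap uses the same exact tail", {
  universe <- sprintf("g%d", 1:8)
  a <- sol(c("g1", "g2", "g3", "g4"), universe = universe)
  b <- sol(c("g1", "g2", "g3", "g8"), universe = universe)
  ov <- shared_gene_overlap(a, b, universe)
  expect_equal(ov$shared, 3)
  expect_equal(ov$p_value, 17 / 70)

  same <- shared_gene_overlap(a, a, universe)
  expect_equal(same$shared, 4)
  disj <- shared_gene_overlap(a, sol(c("g5", "g6"), universe = universe), universe)
  expect_equal(disj$shared, 0)
  expect_equal(disj$p_value, 1)
})

test_that("module consistency applies the 80/80-or-50 rule", {
  ann <- annotation_map(tibble::tibble(gene = c("a", "b", "c"), term = "t"))
  ref <- sol(c("a", "b", "c", "d", "x"), c("e", "f"))
  # 4 of 5 genes in one reference cluster, 3 of 5 share a term
  mc <- module_consistency(c("a", "b", "c", "d", "e"), ref, ann)
  expect_true(mc$consistent)
  expect_equal(mc$reference_fraction, 0.8)
  expect_equal(mc$annotation_fraction, 0.6)

  # ten genes, only 7 sharing a term: fails the 80% annotation bar
  ann10 <- annotation_map(tibble::tibble(gene = sprintf("g%d", 1:7), term = "t"))
  ref10 <- sol(sprintf("g%d", 1:10))
  mc10 <- module_consistency(sprintf("g%d", 1:10), ref10, ann10)
  expect_false(mc10$consistent)

  mc3 <- module_consistency(c("a", "b", "c"), ref, ann)
  expect_true(mc3$consistent)
})

test_that("annotation files and the uncharacterized rule behave", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tt1", "g1\tt2", "g2\tt1"), path)
  ann <- read_annotations(path)
  expect_equal(nrow(ann), 3)
  expect_equal(uncharacterized(ann, c("g1", "g2", "g3")), "g3")
  expect_equal(module_type(c("g1", "g2", "g3"), ann), "type1")
  expect_equal(module_type(c("g1", "g3", "g4"), ann), "type2")
})
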