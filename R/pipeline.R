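#' Run the full screen-to-modules pipeline for several measures
#'
#' For each requested similarity measure: build the score supermatrix
#' (one-square) or work from the raw screen (two-squares), compute all
#' pairwise profile similarities, keep the `k_edges` strongest pairs as
#' a network, extract the giant component, detect modules by recursive
#' edge-betweenness removal, and assess the resulting clustering
#' solution. Solutions are then compared pairwise with the Clustering
#' Error index and shared-gene counts.
#'
#' @param x A [gi_matrix()], a `gi_screen` from [simulate_screen()], or a
#'   [synthetic_config()] (simulated on the fly).
#' @param measures Character vector of [similarity_measures()].
#' @param transformation `"one_square"` or `"two_squares"`.
#' @param k_edges Edges retained by [build_top_k_network()].
#' @param min_size,max_size Module size bounds for
#'   [girvan_newman_clustering()].
#' @param annotations Optional annotation table; taken from the screen
#'   when `x` is synthetic.
#' @param threshold Binarization threshold for the binary measures.
#' @param out_dir Optional directory; when given, every intermediate
#'   artifact (similarity matrices, edge lists, clusterings, the report
#'   tables and the resolved configuration) is written there as
#'   tab-separated text.
#' @return A `gi_report`: list with `similarity_summaries`,
#'   `network_summaries`, `module_summaries` (tibbles, one row per
#'   measure), `ce_matrix` (symmetric, zero diagonal), `shared_genes`
#'   (pairwise tibble), `clusterings` (named list of `gi_clustering`)
#'   and `universe`.
#' @export
run_pipeline <- function(x,
                         measures = c("braun_blanquet_max", "maryland_bridge",
                                      "ochiai", "pearson"),
                         transformation = c("one_square", "two_squares"),
                         k_edges = 20000,
                         min_size = 5, max_size = 50,
                         annotations = NULL,
                         threshold = 0.5,
                         out_dir = NULL) {
  transformation <- match.arg(transformation)
  measures <- vapply(measures, match.arg, character(1),
                     choices = similarity_measures())
  if (inherits(x, "gi_synthetic_config")) x <- simulate_screen(x)
  if (inherits(x, "gi_screen")) {
    annotations <- annotations %||% x$annotations
    m <- x$matrix
  } else if (inherits(x, "gi_matrix")) {
    m <- x
  } else {
    abort("`x` must be a gi_matrix, gi_screen or synthetic_config")
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  universe <- gene_universe(m)
  R <- if (transformation == "one_square") build_one_square(m) else NULL

  stage <- function(what, measure, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed for measure '%s': %s",
                    what, measure, conditionMessage(e)))
    })
  }

  results <- purrr::map(measures, function(ms) {
    S <- stage("similarity", ms, {
      if (transformation == "one_square") {
        similarity_one_square(R, ms, threshold)
      } else {
        similarity_two_squares(m, ms, threshold)
      }
    })
    net <- stage("network", ms, build_top_k_network(S, k_edges))
    giant <- stage("giant_component", ms, giant_component(net))
    clust <- stage("community", ms,
                   girvan_newman_clustering(giant, min_size, max_size))
    if (!is.null(out_dir)) {
      tag <- paste0(ms, "_", transformation)
      write_similarity_matrix(S, file.path(out_dir, paste0("similarity_", tag, ".tsv")))
      write_edge_list(net, file.path(out_dir, paste0("network_", tag, ".tsv")))
      write_clustering(clust, file.path(out_dir, paste0("clustering_", tag, ".tsv")))
    }
    list(measure = ms,
         similarity_summary = similarity_summary(S),
         network_summary = network_summary(net, giant),
         giant = giant,
         clustering = clust)
  })
  names(results) <- measures

  sim_sum <- purrr::map_dfr(results, "similarity_summary")
  net_sum <- dplyr::bind_cols(
    tibble(measure = measures),
    purrr::map_dfr(results, "network_summary")
  )

  mod_sum <- purrr::map_dfr(results, function(r) {
    cl <- r$clustering
    giant_n <- igraph::vcount(r$giant$graph)
    out <- glance(cl)[, c("n_modules", "n_genes_in_modules")]
    out$measure <- r$measure
    out$pct_of_giant <- 100 * out$n_genes_in_modules / max(1L, giant_n)
    if (!is.null(annotations) && length(cl$modules) > 0) {
      out$bhi <- tryCatch(bhi_solution(cl, annotations), error = function(e) NA_real_)
      enr <- uncharacterized_enrichment(cl, annotations, universe)
      out$pct_uncharacterized <- 100 * enr$proportion
      out$enrichment_direction <- enr$direction
      out$enrichment_p <- enr$p_value
      out$modules_with_uncharacterized <- enr$modules_with_uncharacterized
    }
    dplyr::relocate(out, "measure")
  })

  n_m <- length(measures)
  ce <- matrix(0, n_m, n_m, dimnames = list(measures, measures))
  shared <- NULL
  if (n_m > 1) {
    for (i in seq_len(n_m - 1)) {
      for (j in (i + 1):n_m) {
        a <- results[[i]]$clustering
        b <- results[[j]]$clustering
        if (length(a$modules) > 0 && length(b$modules) > 0) {
          ce[i, j] <- ce[j, i] <- clustering_error(a, b)
          ov <- shared_gene_overlap(a, b, universe)
        } else {
          ce[i, j] <- ce[j, i] <- NA_real_
          ov <- tibble(n_a = length(module_genes(a)), n_b = length(module_genes(b)),
                       shared = NA_integer_, p_value = NA_real_)
        }
        shared <- dplyr::bind_rows(
          shared,
          dplyr::bind_cols(tibble(measure_a = measures[i], measure_b = measures[j]), ov)
        )
      }
    }
  }

  report <- structure(
    list(similarity_summaries = sim_sum,
         network_summaries = net_sum,
         module_summaries = mod_sum,
         ce_matrix = ce,
         shared_genes = shared,
         clusterings = purrr::map(results, "clustering"),
         universe = universe,
         transformation = transformation,
         k_edges = k_edges),
    class = "gi_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.gi_report <- function(x, ...) {
  cat(sprintf("<gi_report> %s transformation, %d edges retained per network\n\n",
              x$transformation, x$k_edges))
  cat("Similarity summaries:\n")
  print(dplyr::mutate(x$similarity_summaries,
                      dplyr::across(dplyr::where(is.numeric), ~ round(.x, 2))))
  cat("\nNetwork summaries:\n")
  print(x$network_summaries)
  cat("\nModule summaries:\n")
  print(dplyr::mutate(x$module_summaries,
                      dplyr::across(dplyr::where(is.double), ~ signif(.x, 3))))
  if (nrow(x$ce_matrix) > 1) {
    cat("\nClustering Error between solutions:\n")
    print(round(x$ce_matrix, 2))
  }
  invisible(x)
}

#' @export
tidy.gi_report <- function(x, ...) x$module_summaries

#' @export
glance.gi_report <- function(x, ...) {
  tibble(
    n_measures = nrow(x$module_summaries),
    transformation = x$transformation,
    k_edges = x$k_edges,
    total_modules = sum(x$module_summaries$n_modules)
  )
}

write_report <- function(report, out_dir) {
  wr <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  wr(report$similarity_summaries, "similarity_summaries.tsv")
  wr(report$network_summaries, "network_summaries.tsv")
  wr(report$module_summaries, "module_summaries.tsv")
  wr(report$shared_genes %||% tibble(), "shared_genes.tsv")
  ce <- as.data.frame(report$ce_matrix)
  ce <- cbind(measure = rownames(report$ce_matrix), ce)
  wr(ce, "ce_matrix.tsv")
  writeLines(c(
    paste0("transformation\t", report$transformation),
    paste0("k_edges\t", report$k_edges),
    paste0("measures\t", paste(report$network_summaries$measure, collapse = ","))
  ), file.path(out_dir, "run_config.tsv"))
  invisible(report)
}
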