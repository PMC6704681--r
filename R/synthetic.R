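#' Configuration for a synthetic SGA-like screen
#'
#' The generator plants functional modules in a screen the way the
#' profile-similarity premise expects them to appear: the genes of a
#' module do not interact with *each other* but with a shared set of
#' interaction partners, so that their interaction profiles — and hence
#' their pairwise similarities — are high. Partner sets are drawn from
#' the whole gene universe outside the module, so genes of one module
#' can serve as interaction partners ("hubs") of another; this is what
#' keeps the thresholded similarity network connected into one giant
#' component, as observed in real genome-scale screens.
#'
#' Whether a pair of genes truly interacts is decided once per unordered
#' pair; both tested orientations of an interacting pair then draw a
#' score above the binarization threshold (from `hit_score_range`), and
#' non-interacting tested pairs draw low-magnitude, possibly negative,
#' noise scores (`noise_score_range`).
#'
#' @param n_modules Number of planted modules.
#' @param module_size_range Inclusive size range of a module (genes).
#' @param partners_per_module Size of each module's shared partner set.
#' @param n_background_genes Genes outside any planted module.
#' @param query_fraction,array_fraction Probability that a gene enters
#'   the query / array set; overlap between the sets arises naturally.
#' @param p_within Probability that a module gene truly interacts with
#'   each of its module's designated partners.
#' @param p_background Probability that any other gene pair interacts.
#' @param hit_score_range Score range for interacting pairs; lower bound
#'   must exceed the 0.5 binarization threshold.
#' @param noise_score_range Score range for non-interacting pairs; must
#'   lie strictly inside (-0.5, 0.5).
#' @param frac_unannotated Fraction of module genes left without an
#'   annotation term in the generated annotation table.
#' @param seed Integer seed; the whole screen is a deterministic
#'   function of the configuration.
#' @return A `gi_synthetic_config` list.
#' @export
synthetic_config <- function(n_modules = 8,
                             module_size_range = c(6, 10),
                             partners_per_module = 15,
                             n_background_genes = 200,
                             query_fraction = 1,
                             array_fraction = 1,
                             p_within = 0.95,
                             p_background = 0.005,
                             hit_score_range = c(0.6, 1),
                             noise_score_range = c(-0.25, 0.25),
                             frac_unannotated = 0.15,
                             seed = 1L) {
  cfg <- list(
    n_modules = as.integer(n_modules),
    module_size_range = as.integer(module_size_range),
    partners_per_module = as.integer(partners_per_module),
    n_background_genes = as.integer(n_background_genes),
    query_fraction = query_fraction,
    array_fraction = array_fraction,
    p_within = p_within,
    p_background = p_background,
    hit_score_range = hit_score_range,
    noise_score_range = noise_score_range,
    frac_unannotated = frac_unannotated,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_modules >= 1,
      length(module_size_range) == 2, module_size_range[1] >= 2,
      module_size_range[1] <= module_size_range[2],
      partners_per_module >= 1, n_background_genes >= 0,
      query_fraction > 0, query_fraction <= 1,
      array_fraction > 0, array_fraction <= 1,
      p_within >= 0, p_within <= 1, p_background >= 0, p_background <= 1,
      hit_score_range[1] > 0.5, hit_score_range[1] <= hit_score_range[2],
      noise_score_range[1] > -0.5, noise_score_range[2] < 0.5,
      noise_score_range[1] <= noise_score_range[2],
      frac_unannotated >= 0, frac_unannotated <= 1
    )
  })
  structure(cfg, class = "gi_synthetic_config")
}

#' Simulate a synthetic genetic-interaction screen
#'
#' Generates an interaction matrix with planted modules (see
#' [synthetic_config()]), the ground-truth module memberships, and a
#' matched annotation table carrying one synthetic term per module.
#'
#' @param cfg A [synthetic_config()].
#' @return A `gi_screen`: list with `matrix` (a [gi_matrix()]),
#'   `truth_modules` (list of disjoint gene sets), `annotations`
#'   (annotation tibble) and `config`.
#' @export
simulate_screen <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "gi_synthetic_config"))
  withr::with_seed(cfg$seed, simulate_screen_impl(cfg))
}

simulate_screen_impl <- function(cfg) {
  sizes <- sample(seq(cfg$module_size_range[1], cfg$module_size_range[2]),
                  cfg$n_modules, replace = TRUE)
  n_genes <- sum(sizes) + cfg$n_background_genes
  if (n_genes < max(sizes) + cfg$partners_per_module) {
    abort("infeasible configuration: not enough genes to draw a partner set")
  }
  genes <- sprintf("G%0*d", max(4, nchar(n_genes)), seq_len(n_genes))
  bounds <- cumsum(c(0, sizes))
  truth <- lapply(seq_len(cfg$n_modules), function(i) {
    genes[(bounds[i] + 1):bounds[i + 1]]
  })

  background <- genes[(bounds[cfg$n_modules + 1] + 1):n_genes]
  partners <- draw_partner_sets(truth, background, cfg$partners_per_module)

  # pair-level interaction truth over the upper triangle
  interacts <- matrix(FALSE, n_genes, n_genes, dimnames = list(genes, genes))
  ut <- upper.tri(interacts)
  interacts[ut] <- stats::runif(sum(ut)) < cfg$p_background
  for (i in seq_len(cfg$n_modules)) {
    gi <- match(truth[[i]], genes)
    pi <- match(partners[[i]], genes)
    hit <- matrix(stats::runif(length(gi) * length(pi)) < cfg$p_within,
                  length(gi), length(pi))
    # write planted pairs into the upper triangle, overriding background
    for (a in seq_along(gi)) {
      for (b in seq_along(pi)) {
        r <- min(gi[a], pi[b]); c <- max(gi[a], pi[b])
        interacts[r, c] <- hit[a, b]
      }
    }
  }
  interacts <- interacts | t(interacts)

  in_query <- stats::runif(n_genes) < cfg$query_fraction
  in_array <- stats::runif(n_genes) < cfg$array_fraction
  if (!any(in_query)) in_query[sample(n_genes, 1)] <- TRUE
  if (!any(in_array)) in_array[sample(n_genes, 1)] <- TRUE
  # every truth-module gene must appear in the universe
  orphan <- !(in_query | in_array) & genes %in% unlist(truth)
  if (any(orphan)) {
    to_query <- stats::runif(sum(orphan)) < 0.5
    in_query[orphan][to_query] <- TRUE
    in_array[orphan][!to_query] <- TRUE
  }

  qry <- genes[in_query]
  arr <- genes[in_array]
  x <- matrix(NA_real_, length(qry), length(arr), dimnames = list(qry, arr))
  qi <- match(qry, genes)
  ai <- match(arr, genes)
  hit_cell <- interacts[qi, ai, drop = FALSE]
  same <- outer(qi, ai, "==")
  n_cells <- length(x)
  lo_h <- cfg$hit_score_range[1]; hi_h <- cfg$hit_score_range[2]
  lo_n <- cfg$noise_score_range[1]; hi_n <- cfg$noise_score_range[2]
  draws <- stats::runif(n_cells)
  x[] <- ifelse(hit_cell, lo_h + draws * (hi_h - lo_h),
                lo_n + draws * (hi_n - lo_n))
  x[same] <- NA_real_

  ann <- purrr::map2_dfr(truth, seq_along(truth), function(mod, i) {
    tibble(gene = mod, term = sprintf("MOD%03d", i))
  })
  n_drop <- round(cfg$frac_unannotated * nrow(ann))
  if (n_drop > 0) ann <- ann[-sample(nrow(ann), n_drop), , drop = FALSE]

  structure(
    list(matrix = gi_matrix(x), truth_modules = truth,
         partner_sets = partners,
         annotations = annotation_map(ann), config = cfg),
    class = "gi_screen"
  )
}

# Partner-set design. Planted modules are wired into one connected
# similarity network -- mirroring the single giant component of real
# genome-scale screens -- along a ring over the modules:
#   * a "hub" gene: one gene of the next module serves as an interaction
#     partner of this module. Each module thereby has exactly one
#     gateway gene whose profile straddles two neighbourhoods, tying its
#     clique of mutually similar profiles to the rest of the network;
#   * shared background partners: consecutive modules' partner sets
#     share a small number of background partners, linking the partner
#     neighbourhoods of the ring to each other redundantly.
# All remaining background partners are module-exclusive. Exclusivity
# matters: a partner serving several modules is hit by all their genes,
# and a stray low-support background gene that also hits it becomes
# similar to every member of each of those modules at once, welding
# otherwise unrelated modules together under containment-sensitive
# similarity measures. Sharing is therefore confined to ring neighbours.
draw_partner_sets <- function(truth, background, p, n_shared = 2) {
  n_mod <- length(truth)
  if (n_mod == 1) {
    if (length(background) < p) abort("infeasible configuration: not enough background genes for a partner set")
    return(list(sample(background, p)))
  }
  if (n_mod == 2) n_shared <- 1
  per_module_shared <- if (n_mod == 2) n_shared else 2 * n_shared
  n_excl <- p - 1 - per_module_shared   # hub + shared + exclusive
  if (n_excl < 0) abort("infeasible configuration: partners_per_module too small for the ring design")
  need <- n_mod * n_shared + n_mod * n_excl
  if (length(background) < need) {
    abort(sprintf("infeasible configuration: need %d background genes for partner sets, have %d",
                  need, length(background)))
  }
  pool <- sample(background, need)
  shared <- split(pool[seq_len(n_mod * n_shared)],
                  rep(seq_len(n_mod), each = n_shared))  # shared[[i]] links P_i, P_{i+1}
  excl_pool <- pool[-seq_len(n_mod * n_shared)]
  lapply(seq_len(n_mod), function(i) {
    nxt <- i %% n_mod + 1
    prv <- (i - 2) %% n_mod + 1
    sh <- if (n_mod == 2) shared[[1]] else unique(c(shared[[i]], shared[[prv]]))
    excl <- if (n_excl > 0) excl_pool[((i - 1) * n_excl + 1):(i * n_excl)] else character()
    c(sample(truth[[nxt]], 1), sh, excl)
  })
}

#' @export
print.gi_screen <- function(x, ...) {
  cat(sprintf("<gi_screen> %d planted modules (%d genes) + %d background genes; %d x %d screen\n",
              length(x$truth_modules), length(unlist(x$truth_modules)),
              x$config$n_background_genes,
              nrow(x$matrix$scores), ncol(x$matrix$scores)))
  invisible(x)
}

#' How well a detected clustering recovers the planted modules
#'
#' For each planted module, the best Jaccard index against any detected
#' module; a module counts as recovered when that best Jaccard reaches
#' `j_min`.
#'
#' @param detected A `gi_clustering`.
#' @param truth List of gene sets (e.g. `screen$truth_modules`).
#' @param j_min Jaccard threshold for calling a module recovered.
#' @return List with `per_module` (tibble: `truth_module`, `size`,
#'   `best_jaccard`, `recovered`) and `fraction_recovered`.
#' @export
recovery_report <- function(detected, truth, j_min = 0.8) {
  stopifnot(inherits(detected, "gi_clustering"), length(truth) > 0)
  per <- purrr::map2_dfr(truth, seq_along(truth), function(tm, i) {
    best <- 0
    for (dm in detected$modules) {
      j <- length(intersect(tm, dm)) / length(union(tm, dm))
      if (j > best) best <- j
    }
    tibble(truth_module = i, size = length(tm), best_jaccard = best,
           recovered = best >= j_min)
  })
  list(per_module = per, fraction_recovered = mean(per$recovered))
}
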