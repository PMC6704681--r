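---
title: "Profile-similarity networks and gene modules from genetic interaction screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-similarity networks and gene modules from genetic interaction screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ginprof)
```

## The analysis in one paragraph

A quantitative genetic-interaction screen crosses a set of query gene
deletions against an array of deletion mutants and scores the fitness of
every double mutant. Each gene is then described by its *interaction
profile* — the vector of its scores against all partners — and two genes
are linked in a network when their profiles are similar, whether or not
they interact directly. `ginprof` implements this inference chain as
composable steps: build a symmetric gene-by-gene score supermatrix from
the rectangular screen, compute all pairwise profile similarities under a
chosen measure, keep the top-*k* strongest pairs as an undirected
weighted network, discard everything outside the giant connected
component, and collect gene modules of 5–50 genes by recursive
edge-betweenness (Girvan–Newman) removal. Because the choice of
similarity measure changes which modules appear, the package also
quantifies how much two clustering solutions differ (Clustering Error via
optimal assignment), how biologically coherent each is (Biological
Homogeneity Index against a functional annotation table), and whether a
solution is enriched for unannotated genes (exact hypergeometric tests).

## From screen to supermatrix

The raw screen is a query-by-array matrix `X` whose cells may be missing
(never measured). Two routes lead to a symmetric object:

* **one-square**: every measured score is placed into a symmetric
  supermatrix `R` over the union of query and array genes. When both
  orientations of a pair were measured, the two scores are averaged;
  never-tested pairs are set to 0 and flagged in a `measured` mask.
  Similarities are then computed between rows of `R`.
* **two-squares**: similarities are computed separately between query
  rows (`Q`) and between array columns (`A`) of `X`, then merged over
  the gene universe, averaging entries present in both blocks. A pair
  with one query-only and one array-only gene has no value in either
  block and is flagged undefined; such pairs never become edges.

A gene screened under several conditions must arrive with distinct
labels (for example `GENE__27C`); the reader never merges labels. All
gene-by-gene matrices are emitted in lexicographic gene order so that
runs are reproducible file-to-file.

## Similarity measures

For binary profiles (scores dichotomized at a threshold of 0.5, strict
`>`), with `a` the number of shared 1s and `|x|`, `|y|` the support
sizes:

| measure | value |
|---|---|
| Maryland bridge | `(a/|x| + a/|y|)/2` |
| Ochiai | `a / sqrt(|x| |y|)` |
| Braun-Blanquet (max / min) | `a / max(|x|,|y|)`, `a / min(|x|,|y|)` |
| Dice | `2a / (|x|+|y|)` |
| Jaccard | `a / (|x|+|y|-a)` |

Pearson correlation operates on the raw real-valued profiles. Useful
identities, all verified by the test suite over random profiles: Ochiai
is the geometric and Dice the harmonic mean of the two Braun-Blanquet
coefficients, and for profiles with non-empty supports
`BBmax <= Dice <= Ochiai <= Mb <= BBmin`. The Dice denominator is
written here as `|x|+|y|`; this is the form consistent with the
harmonic-mean identity and with the property that two equal-support
profiles sharing half their 1s score 0.5 under both Mb and Dice (the
same pair scores the famously counter-intuitive 1/3 under Jaccard).

Conventions for degenerate input, chosen so that similarity matrices
stay total and runs never divide by zero: a binary profile with empty
support has similarity 0 to everything (no shared interactions), and a
constant profile has Pearson similarity 0, flagged as undefined in the
`defined` mask so summaries and networks can exclude it. A score exactly
equal to the binarization threshold maps to 0, making the dichotomy
reproducible. Summary statistics (mean, population variance, median,
extremes) use defined, off-diagonal, upper-triangle entries only —
self-similarities of 1 would otherwise distort them.

## Network construction and module detection

`build_top_k_network()` ranks all defined off-diagonal pairs by weight
(descending) and keeps exactly `k` edges; ties at the boundary are
broken by lexicographic gene-pair order so replications are exact. The
weight of the rank-`k` edge is reported as the network's threshold. The
default `k = 20000` matches the conventional size for a genome-scale
screen of several thousand genes; at that scale the retained edges are a
small fraction of all scored pairs. Smaller unconnected islands are then
discarded by `giant_component()` (size ties broken toward the component
with the lexicographically smallest label).

`girvan_newman_clustering()` implements recursive edge-betweenness
removal on the unweighted graph: compute the betweenness of every edge
(shortest-path counting with equal splitting among tied paths), delete
the single most-used edge (ties again lexicographic), and repeat until
no edges remain. Every connected component whose size falls within
`[min_size, max_size]` at *any* step — including the initial state — is
recorded; the deduplicated union of recorded components is the
clustering solution. Modules may therefore be nested: a component
recorded early often fragments into smaller recordable pieces. The 5–50
default range reflects the sizes expected of functional gene modules.
Betweenness is computed on the unweighted graph because edge weights
here mean *closeness*: treating them as path lengths would invert their
sense. A weighted mode (length `1/weight`) is available behind a flag.
Components that fall below `min_size` are pruned from further
processing; no component can grow, so this cannot change the result
(the suite checks this equivalence against the unpruned reference), it
only shortens the tail of the recursion.

## Comparing and assessing clustering solutions

The Clustering Error between solutions `S` and `S'` is
`CE = (|U| - D)/|U|`, where `U` is the set of distinct genes appearing
in any module of either solution and `D` is the maximal total overlap
under a one-to-one matching of modules, computed from the confusion
matrix by the Hungarian method. `|U|` is deliberately a set size: a
multiset reading would make `CE(S, S)` nonzero for solutions with nested
modules, contradicting the defining property that identical solutions
score 0. For the same reason the index is clamped at 0: with nested or
overlapping modules the matched total `D` counts a gene once per module
pair it appears in and can exceed `|U|`, so the raw ratio would go
negative exactly where the definition intends "perfect agreement".

The Biological Homogeneity Index of a cluster is the probability that
two annotated genes in it share at least one functional term; clusters
with fewer than two annotated genes are undefined and are dropped from
the solution-level average. Annotations are a flat two-column gene-term
table; no ontology hierarchy is applied, so users who want ancestor
terms must pre-propagate them. Enrichment of unannotated
("uncharacterized") genes in a solution is tested with the exact
hypergeometric tail in the direction of the observed deviation; the
universe to test against (all screened genes versus giant-component
genes) is a choice the user makes by passing the appropriate vector.
The module-consistency rule asks whether at least 80% of a module's
genes co-occur in a single reference cluster *and* whether one
annotation term is shared by at least 80% of its genes (50% for modules
under 10 genes). The type-1/type-2 labelling implemented here is an
annotation-share proxy (more than half of the genes sharing one term);
it approximates, but is not, a manual literature curation.

## The synthetic screen generator

Real screens of this kind are large (thousands of genes) and external,
so the package ships a generator that plants known modules in a
realistic screen shape; every pipeline stage is tested against planted
truth. The model follows the premise of profile-similarity inference: a
module's genes do not interact with each other — they share a
*designated partner set*, so their profiles, and hence their pairwise
similarities, are high. Whether a pair truly interacts is decided once
per unordered pair (`p_within` for module-partner pairs, `p_background`
for everything else); each tested orientation of an interacting pair
then draws a score from `hit_score_range` (above the 0.5 binarization
threshold), and non-interacting tested pairs draw low-magnitude,
possibly negative, noise from `noise_score_range`. Deciding truth at
the pair level matters: reciprocal averaging would otherwise pull half
of the singly-hit pairs below threshold and silently lower the
effective penetrance.

Partner sets are laid out along a ring over the modules. One gene of
the next module serves as a partner of the current module (a "hub"), so
each module has exactly one gateway gene tying it into the rest of the
network; consecutive partner sets additionally share two background
partners, linking the partner neighbourhoods redundantly; all other
background partners are module-exclusive. This layout was chosen over
the obvious alternatives for specific reasons. Fully exclusive partner
sets produce a similarity graph that decomposes into disconnected
cliques, so the giant-component step — which real networks motivate:
their giant components cover nearly all nodes — would discard most
planted modules. Heavily shared partner pools (or partner sets made of
other modules' genes wholesale) overconnect the graph: modules acquire
more external than internal edges and edge-betweenness removal can no
longer carve them out cleanly. Sharing confined to ring neighbours,
with a single gateway gene per module, keeps the network connected
while bounding what module detection can lose — typically the gateway
gene itself, whose profile straddles two neighbourhoods. A related
caveat: under full penetrance (`p_within = 1`, `p_background = 0`) two
genes of the same module have identical binary profiles and similarity
exactly 1 under every binary measure, *except* pairs involving the
module's hub gene, whose profile legitimately contains its served
neighbourhood as well.

Defaults follow the scale the package is tested at: 8 modules of 6–10
genes, 15 partners per module, 200 background genes, `p_within = 0.95`,
`p_background = 0.005`, every gene on both axes, hit scores in
(0.6, 1), noise in (−0.25, 0.25) — small negative scores mimic the
signed score scale of real screens — and 15% of module genes left
unannotated, comparable to the unannotated fraction of a well-studied
genome. Gene labels are zero-padded so generation order and
lexicographic order coincide. `recovery_report()` scores a detected
clustering by the best Jaccard index each planted module achieves,
counting a module as recovered at Jaccard ≥ 0.8.

What the generator does *not* emulate: batch effects, linkage of array
genes to the query locus, replicate conditions beyond label suffixes,
and the long-tailed degree structure of real interaction networks.
Passing the recovery tests therefore demonstrates that the chain of
transformations preserves planted profile structure under noise, not
that any particular biological screen will yield modules of comparable
quality.

## Problem sizes and costs

The test suite and the acceptance script run the full pipeline on
screens of roughly 260 genes (about 34,000 scored pairs, networks of
around a thousand edges). These sizes were chosen so that a complete
run — generation, similarity, thresholding, and the full quadratic-cost
betweenness recursion, for several measures — completes in minutes while
leaving every stage's behaviour measurable. The same code paths run
unchanged on a deposited genome-scale screen; only the Girvan–Newman
stage becomes expensive there (its cost grows roughly as edges ×
nodes × removals), which is why module detection on a 20,000-edge
network of several thousand genes is an overnight computation rather
than a test-suite one.

## Known limitations

* The two-squares merge treats the query and array blocks as equally
  informative; no weighting by measurement count is attempted.
* Betweenness ties are broken lexicographically; a different tie rule
  can shift which of several equivalent modules is recorded first,
  though the recorded *set* is stable in practice because all
  components in range are collected at every step.
* The uncharacterized-gene tests assume the annotation table is
  complete for annotated genes; partially annotated genomes shift the
  universe rate rather than the solution rate.
* `bb_min` rewards containment: any low-support gene whose few hits
  fall inside a hub's support scores 1.0, so top-k networks under
  `bb_min` are dominated by containment pairs. The coefficient is
  provided (and its identities tested), but it is a poor choice for
  thresholded network construction, and the pipeline defaults steer to
  the max-normalized variant.
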