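Package: ginprof
Title: Profile-Similarity Networks and Modules from Genetic Interaction Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning a quantitative genetic-interaction screen
    (query x array score matrix, as produced by Synthetic Genetic Array
    experiments) into gene similarity networks under several
    profile-similarity measures (Maryland bridge, Ochiai, Braun-Blanquet,
    Dice, Jaccard, Pearson), detecting 5-50 gene modules by recursive
    edge-betweenness (Girvan-Newman) removal, and comparing the resulting
    clustering solutions with the Clustering Error index (optimal
    assignment), the Biological Homogeneity Index, and exact
    hypergeometric enrichment tests. Includes a synthetic screen
    generator with planted modules so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    clue,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
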