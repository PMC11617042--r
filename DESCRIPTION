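Package: mucohub
Title: Compositional Co-Occurrence Networks and Hub Taxa for Mucosal Microbiome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for two-condition mucosal
    microbiome studies. Infers taxon-taxon basis correlations from
    compositional count tables by iterative log-ratio variance
    decomposition (SparCC-style), builds thresholded signed co-occurrence
    networks, classifies their degree distributions as power-law
    (scale-free) or Poisson (random), and detects hub taxa whose degree
    strictly exceeds the third quartile of the network degree
    distribution. Also provides alpha diversity, Bray-Curtis ordination
    with PERMANOVA, rank-based differential-abundance screening with
    LDA-style effect sizes, covariate-adjusted per-feature linear models,
    Spearman association of taxa with host phenotypes, and a synthetic
    study generator with planted network topology for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    igraph,
    generics,
    jsonlite,
    stats,
    utils,
    pracma,
    vegan
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
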