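Package: tptnet
Title: Target-Pathway-Target Networks for Network Pharmacology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds targets-(pathways)-targets (TPT) networks from bipartite
    target-pathway annotations, partitions them into modules by Louvain
    modularity optimisation, scores the contribution of each module toward
    diseases through shared pathway support, validates module-disease
    association with chi-square tests and approved-drug ATC classes, and
    ranks targets inside a module by an integrated centrality indicator
    (target importance). Includes a planted-module synthetic data generator
    and a hypergeometric over-representation stage for pathway filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
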