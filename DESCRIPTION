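Package: tripnet
Title: Tripartite Regulatory Network Prioritization of Non-Coding RNA
    Biomarkers Shared Between Two Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for nominating microRNA and long non-coding
    RNA biomarkers shared between two complex traits (such as diabetes
    mellitus and Alzheimer's disease) from genome-wide association summary
    statistics. Per-trait variants are filtered on minor-allele frequency,
    adjusted with the Benjamini-Hochberg false-discovery-rate procedure, and
    intersected across traits; shared significant variants are connected
    into a linkage-disequilibrium graph (D' and chi-squared p-value
    thresholds), from which dense-subgraph "signatures" are enumerated and
    mapped to genes. Protein-microRNA and microRNA-lncRNA bipartite networks
    are built from interaction tables, hub nodes selected by tie-extended
    top-degree ranking, edges validated by multi-database evidence
    consensus, and the resulting tripartite network scored with an exact
    rational degree-normalized scoring function to rank candidate
    biomarkers. A seeded synthetic-data generator emulates every input so
    the whole pipeline is testable offline.
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
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
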