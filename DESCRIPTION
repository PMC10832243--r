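Package: netpharm
Title: Network Pharmacology Analysis of Multi-Herb Formulas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for network pharmacology of multi-component
    herbal formulas. Screens candidate compounds for oral activity with
    ADME criteria (Lipinski's rule of five plus oral bioavailability,
    drug-likeness, Caco-2 permeability and rotatable-bond cutoffs),
    aggregates predicted compound targets across sources, intersects them
    with disease gene sets, selects hub genes from protein-protein
    interaction networks by median cutoffs on degree, betweenness and
    closeness centrality, ranks compounds in herb-compound-target networks,
    and performs hypergeometric over-representation analysis with
    Benjamini-Hochberg correction. Includes seed-reproducible synthetic-data
    generators with known ground truth for every pipeline stage, and a
    curated reference data set for the three-herb formula SH003 in the
    context of non-small cell lung cancer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
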