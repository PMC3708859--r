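Package: sidefxnet
Title: Network Determinants of Drug Side-Effect Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline relating the number of side effects a drug
    causes to properties of its protein targets: essentiality, degree and
    betweenness centrality in a quality-filtered protein-protein interactome,
    sharing of interaction interfaces on a structurally resolved sub-network,
    and network distance between targets and disease-associated genes.
    Provides negative binomial count regressions on median-binned responses,
    bootstrap comparisons of class medians, degree-preserving and
    association-shuffling randomization nulls, and a synthetic-data generator
    with known ground-truth effect sizes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
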