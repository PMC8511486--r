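Package: scnet
Title: Graph-Theoretic Analysis of Gray-Matter Structural Covariance Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and compares group-level structural covariance networks
    from subject-by-region gray-matter volume tables. Regional volumes are
    corrected for age, sex, education and mean overall gray-matter volume by
    per-region linear regression; group Pearson correlation matrices are
    binarized over a grid of edge densities; small-world indices, efficiency
    and betweenness-centrality profiles are computed against degree-matched
    rewired random networks; groups are compared by subject-relabelling
    permutation tests with false-discovery-rate correction; and network hubs
    are identified by the mean-plus-one-standard-deviation betweenness rule.
    Includes a synthetic-cohort generator with known modular covariance
    structure, covariate effects and planted group differences for validation,
    plus export of BrainNet Viewer node/edge files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
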