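Package: cladospace
Title: Construction, Validation and Mapping of Phylogenetic Tree Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sets of cladograms as points in a metric
    tree space. Computes pairwise tree distances under eight metrics,
    including information-theoretic generalizations of the Robinson-Foulds
    distance with optimal split matching, the quartet distance, and
    Euclidean vector metrics (path, Kendall-Colijn at lambda = 0, and the
    split size vector metric). Detects clusters of trees with silhouette
    based model selection, maps tree spaces into few dimensions with a
    suite of multidimensional scaling methods, and - crucially - validates
    mappings with distortion diagnostics (trustworthiness and continuity,
    Shepard correlations, minimum spanning tree extension factor,
    correlation dimension). Also scores stratigraphic congruence of dated
    cladograms via the minimum implied gap, and provides benchmarks of
    metric behaviour (balance independence and saturation) on uniformly
    sampled tree topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    cluster,
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph,
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
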