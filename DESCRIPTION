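Package: vesselrank
Title: Classification and Cluster-Based Ranking of Vascular Tree Segments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for grouping the segments of monopodial vascular trees
    and ranking the groupings by morphometric coherence. Implements four
    branching classifications (generations, Horsfield orders, Strahler
    orders, fractal generations), aggregation of per-slice inner/outer
    diameter measurements into per-segment features, a Gaussian-mixture
    reference clustering with BIC model selection, and a Davies-Bouldin
    cluster-validity ranking of the classification schemes. Includes
    synthetic generators for monopodial and dichotomous trees, measurement
    tables and labeled mixtures so the full pipeline runs without external
    data, plus GraphML/CSV/NRRD input and output and a small command-line
    front end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    mclust,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
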