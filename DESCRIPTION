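Package: mtpconn
Title: Threshold-Robust Inference for Streamline-Count Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for graph-theoretical analysis of structural brain
    networks weighted by streamline counts, with explicit handling of the
    threshold-selection problem. Provides weighted network metrics (global
    efficiency, mean clustering coefficient, mean betweenness centrality,
    smallworldness) computed across streamline-count thresholds; simulators
    of tractography error processes (false positives creating new edges,
    false positives inflating existing edges, edge displacement, and
    interhemispheric atrophy); an adjacent-threshold instability statistic
    for test statistics evaluated along the threshold axis; and the
    multi-threshold permutation correction (MTPC) procedure, a max-statistic
    permutation test with super-critical cluster-area enhancement, together
    with the per-subject area-under-the-curve comparator method and
    minimum-detectable-effect estimation. A synthetic-connectome generator
    with hemispherically mirrored bundle structure makes the whole pipeline
    runnable end-to-end without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
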