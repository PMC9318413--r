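Package: taacgh
Title: Topological Association Analysis of Copy-Number Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting phenotype-associated copy-number aberrations
    in aCGH-style log2-ratio profiles with topological signatures. Chromosome
    arms are cut into overlapping probe segments, each segment is embedded as
    a sliding-window point cloud, and the Vietoris-Rips persistent homology of
    the cloud is summarised as Betti, lifespan, or persistence-landscape
    curves. Segments are tested for association with a phenotype by a
    permutation test on the L2 distance between group-average curves with
    Benjamini-Hochberg FDR control, and significant segments feed
    forward-AIC logistic subtype classifiers. The package also ships the
    simulation engine used to benchmark the curves and exact calculators
    (with brute-force oracles) for bottleneck-distance stability bounds on
    Betti and lifespan curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
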