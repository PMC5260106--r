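Package: rwrscreen
Title: Semi-Supervised Drug Screening by Random Walk with Restart on
    Bipartite Drug-Protein Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate compounds for a phenotype of interest (for
    example lifespan extension in C. elegans) by propagating labels of
    known effective and ineffective drugs over a confidence-weighted
    drug-protein bipartite network.  Two restarting random walks are run
    from the positive and negative seed sets and every node is scored by
    the odds of the two stationary probabilities (the F-ratio).  The
    package also provides chemical (cosine), target-sharing (Jaccard)
    and noisy-OR-integrated drug-drug similarities, a k-nearest-neighbour
    baseline, stratified k-fold cross-validation with recall-precision
    curves, a paired-contrast t-test for screened compounds, a synthetic
    planted-module data generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
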