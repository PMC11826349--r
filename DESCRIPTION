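Package: siteharm
Title: Harmonization of Structural Connectome Network Measures Across
    Acquisition Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for removing scanner- and protocol-specific ("site")
    effects from structural brain connectomes while preserving biological
    signal. Implements a conditional variational autoencoder whose latent
    space is trained to be uninformative of acquisition site but predictive
    of participant age, sex, and twelve weighted graph-theoretic network
    measures (modularity, betweenness, assortativity, participation,
    clustering, strength, local and global efficiency, density, rich club,
    characteristic path length, and path edge count). Trained models project
    connectomes and their network measures into a common site domain of the
    user's choice. Includes readers for delimited connectome matrices,
    a weighted network-measure toolbox, demographic matching, effect-size
    based harmonization benchmarks, bootstrap stability analysis, and a
    synthetic two-site cohort generator with known ground-truth effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
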