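Package: pathmi
Title: Probabilistic Inference and Ranking of Gene Regulatory Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers and ranks linear gene-regulatory pathways from expression
    data by converting path inference into a shortest-path problem. Pairwise
    mutual information is estimated on bootstrap resamples, each edge is
    classified as direct or indirect per round with the data processing
    inequality, and the resulting per-edge probabilities of directness are
    transformed to negative-log weights searched with Dijkstra's algorithm.
    Includes ARACNe-style pruning and a mutual-information minimum spanning
    tree as comparison methods, path-level precision/recall evaluation
    against a ground-truth network, and a simulator that generates networks
    of controllable topology and cyclicity together with nonlinear noisy
    expression data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
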