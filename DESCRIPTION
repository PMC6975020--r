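Package: steadyABC
Title: Causal Orientation of Gene Regulatory Networks by Approximate
    Bayesian Computation over Steady-State Signalling Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the direction (causality) of links in small undirected
    gene regulatory networks from averaged transcriptomics or proteomics
    data. An undirected, signed network is first reconstructed from
    expression tables by Pearson correlation and shrinkage partial
    correlation at a stringent threshold. Every orientation of its links is
    then simulated with a Hill-type steady-state ordinary differential
    equation model under perturbations of the nodes' independent activity;
    per-node logarithmic sensitivities serve as summary statistics and are
    compared by Euclidean distance to a scaled observed log fold-change
    vector. A rejection step keeps the best-matching fraction of simulated
    candidates and the proportion of accepted candidates orienting each
    link yields a posterior probability of link direction. Includes a
    synthetic benchmark generator, strict text-format readers and writers,
    and a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
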