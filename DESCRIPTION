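Package: asrbench
Title: Benchmarking the Effect of Multiple Sequence Alignment on
    Ancestral Sequence Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation-based benchmarking of how multiple sequence
    alignment quality modulates the accuracy of marginal maximum-likelihood
    ancestral sequence reconstruction (ASR) for proteins. Provides an
    ultrametric birth-death tree simulator with species sampling, an
    indel-aware protein sequence evolution simulator (WAG + discrete gamma
    substitutions, Zipfian indel lengths) that records the true all-node
    alignment, a marginal ML reconstruction engine with a two-state
    presence/absence indel model, an accuracy decomposition into insertion,
    deletion and substitution errors, reference-based alignment quality
    scores (sum-of-pairs, modeler, total-column, Cline shift), and an
    orchestration layer for scenario grids, aligner adapters and the
    statistical comparison of aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    phangorn,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
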