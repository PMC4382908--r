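Package: contactmeta
Title: Two-Stage Neural Meta-Prediction of Protein Residue Contacts
Version: 0.1.0
Authors@R: person("Artifact", "Builder", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts residue-residue contacts and directed backbone
    hydrogen bonds from multiple sequence alignments. Combines
    alignment-derived statistics (column profiles, entropies, effective
    sequence counts) with several coevolution channels (mutual
    information, normalized mutual information, mean contact potential,
    mean-field direct coupling analysis and a regularized
    inverse-covariance score) as input to a two-stage feed-forward
    neural network ensemble, where the second stage filters the first
    stage's contact map through a 2D window. Includes training,
    positive-predictive-value calibration, top-L/k precision evaluation
    with redundancy filtering, a synthetic protein-family generator for
    desk-scale end-to-end runs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
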