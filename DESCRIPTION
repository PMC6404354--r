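Package: glycopu
Title: Positive-Unlabelled Bayesian Classifiers for Protein Glycosylation
    Site Prediction
Version: 0.1.0
Authors@R:
    person("glycopu", "maintainers", email = "glycopu@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting protein glycosylation sites when only
    positive (experimentally verified) and unlabelled candidate sites are
    available. Implements sequence-window feature extraction (amino acid and
    dipeptide composition, autocorrelation, composition-transition-
    distribution, sequence-order, pseudo amino acid composition and AAindex
    encodings), minimum-redundancy maximum-relevance feature selection,
    class-prior estimation under the selected-completely-at-random assumption
    (Elkan-Noto and AlphaMax estimators), the positive-unlabelled Bayesian
    classifier family PNB/PAODE/PAnDE/PTAN, evaluation protocols with
    repeated randomized splits and cross-validation, and synthetic data
    generators for end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Matrix,
    methods,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
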