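Package: ldalink
Title: Topic-Model De-Noising and Self-Supervised Link Prediction for
    Paired Host-Gene and Microbe Abundance Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De-noises heterogeneous patient-by-gene and patient-by-microbe
    abundance tables with latent Dirichlet allocation fitted by collapsed
    Gibbs sampling, builds a self-supervised pseudo-gold standard of
    gene-microbe links from extreme linear correlations, and trains a
    random-forest classifier on concatenated topic features to score all
    gene-microbe pairs. Companion modules provide supervised cell-type
    deconvolution by nu-support-vector regression, microbe co-abundance
    network construction with module detection, cross-table correlation
    with Benjamini-Hochberg correction, taxonomy roll-up, and seeded
    synthetic-data generators with retained ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    e1071,
    randomForest,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
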