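Package: ordimir
Title: Covariate-Adjusted Ordination Maps of miRNA-mRNA Co-Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrated analysis of joint miRNA and mRNA expression profiles in
    diseased versus control tissue: multivariate permutation F-tests with
    false-discovery-rate confidence control, pairwise Kendall tau-b and
    first-order partial Kendall correlations that remove a histopathological
    covariate (e.g. the degree of hepatic necrosis), transformation of
    correlations into zero-centered nonmetric distances, classical
    multidimensional scaling computed by singular value decomposition, and
    map-level thematic statistics (dispersion ellipses, density
    complementarity, median-correlation shifts, miRNA-mRNA target-pair
    distance analysis with a sign-flip control, mirSVR-distance regression,
    and seed-sequence grouping). A synthetic-study generator with full ground
    truth emulates the confounded case/control design so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    MASS,
    vegan,
    yaml,
    digest,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
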