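Package: chimic
Title: Maximal Information Coefficient with Chi-Square-Terminated Grid Search
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes the maximal information coefficient (MIC) between two
    numeric variables with two grid-search strategies: the classical
    ApproxMaxMI dynamic-programming sweep under the B(n) = n^a maximal
    grid-size bound, and ChiMIC, a sequential endpoint-insertion search that
    terminates each axis partition with a chi-square independence test on the
    two columns flanking the newest endpoint. Also provides the minimum cell
    number (MCN) complexity statistic, seeded generators for independent
    pairs and noisy functional relationships, and a permutation-null
    statistical-power harness for arbitrary bivariate statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
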