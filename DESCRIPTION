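Package: mdmreg
Title: Multivariate Distance Matrix Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relates M predictor variables to an N x N distance matrix
    computed over P outcome variables (P may greatly exceed N), using the
    pseudo F-statistic of multivariate distance matrix regression (MDMR).
    Provides distance-matrix construction with pairwise-complete handling of
    missing values, Gower double-centering, QR-based projection onto the
    predictor space, permutation and analytic F-distribution p-values,
    Monte-Carlo drivers for test level accuracy and power, and an MDMR-based
    procedure for choosing the number of clusters, with a UPGMA baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
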