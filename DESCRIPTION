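Package: qparscreen
Title: Joint-Action Modelling and Good2bad Screening of Bioactive Components
    in Herbal Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative pattern-activity relationship (QPAR) screening of
    candidate bioactive components from chromatographic fingerprints.
    Provides Hill dose-response algebra (effect prediction, ECx inversion,
    two-point and least-squares fitting), joint-action mixture models
    (concentration addition, response addition and the Olmstead cassette
    model), global-search parameter estimation with a partial least squares
    baseline, UV-spectrum correlation and k-means cassette assignment,
    Monte Carlo subset sampling with Good2bad feature ranking,
    uniform-design mixture construction utilities, and a seeded synthetic
    data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
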