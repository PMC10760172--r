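Package: nichekit
Title: Presence-Background Niche Models and Niche-Overlap Permutation Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for asking whether two or three closely related taxa --
    typically the parental forms and hybrids of a hybrid zone -- occupy
    different environmental niches.  Provides a presence-background
    maximum-entropy (maxent-style) niche model with L1 regularization,
    replicated AUC validation, percent contribution and permutation
    importance; Schoener's D, Hellinger distance and Warren's I niche-overlap
    statistics; the niche identity test and the blob range-breaking
    permutation test; eBird-style checklist filtering, spatial thinning,
    sample-size balancing and target-group background selection; and a
    synthetic-data module that simulates spatially autocorrelated
    environmental layers and occurrence records from Gaussian niche-response
    surfaces, so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
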