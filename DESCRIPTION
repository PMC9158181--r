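Package: sorequiv
Title: Equivalence Testing Between Feature Lists via the Sorensen-Dice
    Index of Joint Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests whether two (or more) feature lists, e.g. gene lists
    from omics experiments, are biologically equivalent up to an
    irrelevance threshold, based on the Sorensen-Dice dissimilarity
    computed from the 2x2 contingency table of joint GO-term enrichment.
    Provides the asymptotic-normal test derived by the delta method, a
    studentized-bootstrap variant with better small-sample calibration,
    Holm-corrected all-pairs comparison of several lists, a Mantel
    permutation test for comparing triangular test-output matrices, an
    over-representation front-end that turns raw gene lists into binary
    enrichment profiles, and a Monte-Carlo engine for type-I error and
    power studies of both test flavours.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
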