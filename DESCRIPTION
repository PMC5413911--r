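Package: tempenrich
Title: Temporal Expression Profile Clustering and Responsive Gene-Set
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Clusters stage-course embryo expression profiles (FPKM across
    ordered developmental stages) with fuzzy c-means, collapses correlated
    clusters into temporal profiles, builds up/down responsive gene sets
    from a differential-expression table by adjusted p-value, endpoint
    expression and fold-change filters, and identifies profiles enriched or
    depleted for responsive genes by a stepwise Pearson chi-square procedure
    with exact hypergeometric (Fisher) tests, individually and combined. A
    seeded synthetic-data generator produces stage matrices, differential
    expression tables and spiked responsive sets with known ground truth so
    the whole pipeline can be exercised and calibrated without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    mclust,
    optparse
Config/testthat/edition: 3
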