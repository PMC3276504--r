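Package: sigreverse
Title: Functional-Signature Reversal for Drug Repositioning
Version: 0.1.0
Authors@R:
    person("sigreverse", "maintainers", email = "maintainers@sigreverse.org",
           role = c("aut", "cre"))
Description: Identifies bioactive compounds whose strongest expression
    perturbations reverse-correlate with a disease's strongest differential
    expression. Disease tissue profiles and compound-perturbation rank
    profiles (Connectivity-Map style) are reduced to ranked gene lists; the
    top and bottom k genes of each list are compared with one-sided
    hypergeometric (Fisher) overlap tests under Benjamini-Hochberg false
    discovery rate control; the window size k is optimized against known
    drugs by a sensitivity/specificity rule; and candidate gene windows are
    interpreted with hypergeometric gene-set over-representation. Includes
    readers for GDS-style expression tables, rank matrices, GMT gene sets
    and drug annotations, plus a synthetic-data generator so the whole
    pipeline runs self-contained.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
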