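Package: mirbic
Title: Progressive Bicluster Extension for Condition-Specific miRNA Target Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovers condition-specific miRNA regulatory modules from large
    compendia of binarized expression fold changes.  Sequence-predicted target
    genes of a miRNA are assembled into a binary MIR profile over
    enrichment-selected cell conditions; exact all-1 seed biclusters are
    extracted with the BIMAX divide-and-conquer recursion and grown with a
    noise-tolerant progressive bicluster extension (PBE) under a ramped
    zero-proportion threshold; redundant results are merged by average-linkage
    clustering of Meet/Min distances and trimmed.  Includes a planted-bicluster
    simulation benchmark with element-level precision and sensitivity, and
    gold-standard evaluation utilities (sensitivity, specificity, gain in
    certainty, protein-interaction degree filtering, pooled condition-
    proportion curves).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
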