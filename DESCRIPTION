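Package: pcnet
Title: Pathway Co-Expression Networks and Redundancy Analysis for Tumor Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds FDR-controlled gene co-expression networks from two-group
    expression data, aggregates them into pathway-level crosstalk networks with
    permutation-resampled edge significance, and quantifies three redundancy
    mechanisms (redundant genes, redundant 3-node crosstalk circles, redundant
    category circles) together with node-deletion intervention metrics for
    comparing drug target sets. Includes a synthetic two-group data generator
    with planted within- and cross-pathway correlation blocks so the whole
    pipeline runs and is testable without any external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
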