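Package: sigrev
Title: Transcriptomic Signature Reversal for Computational Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A connectivity-mapping toolkit for matching drug perturbation
    signatures against disease expression profiles. Builds moderated-t
    differential signatures from treated/control count matrices, extracts
    up/down tag sets and ranked lists, scores drug-disease pairs with the
    signed Kolmogorov-Smirnov connectivity statistic under a permutation
    null with Benjamini-Hochberg FDR, calls cross-condition inverse
    concordance, ranks compounds by library percentile, validates
    directionality with weighted gene set enrichment, and infers upstream
    regulators through a transcription-factor / protein-interaction-network /
    kinase enrichment chain. Includes a negative-binomial synthetic-data
    generator with planted drug-disease reversal structure for end-to-end
    validation, plus NAFLD activity score utilities for histology tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
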