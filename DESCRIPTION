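Package: acscan
Title: Catalytic-Centre Motif Search for Candidate Nucleotide Cyclases
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting candidate adenylate- and guanylate-cyclase
    catalytic centres in protein sequences. Provides a position-annotated
    motif model using PROSITE-style bracket patterns with bounded wildcard
    gaps, derivation operators (substrate-specificity substitution, gap
    constraining, upstream anchor filters), an exhaustive variable-gap
    scanner over FASTA proteomes that reports every overlapping occurrence,
    a closed-form background model for expected chance hits, a planted-motif
    simulator supplying ground truth for scanner validation, and a
    co-expression module that ranks genes by Pearson correlation to a query
    gene and exports log2 fold-change tables for condition heatmaps. A
    command-line interface exposes scanning, preset listing, simulation and
    co-expression ranking for pipeline use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
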