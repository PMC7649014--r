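Package: notchfam
Title: Evolutionary Sequence Analysis of the Notch Receptor Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable re-implementation of a Notch-family
    protein evolution workflow: curation of noisy protein FASTA sets
    (keyword filters, reference local-alignment screening, 95% identity
    deduplication), Gonnet-scored progressive multiple sequence alignment
    over a neighbour-joining guide tree, protein Jukes-Cantor distances with
    UPGMA clustering and threshold sub-family extraction, bootstrapped
    consensus-level phylogenies, and a PROSITE-style motif grammar with
    EGF-like repeat detection by cysteine spacing, calcium-binding EGF
    classification and a per-receptor digital (0/1) calcium signature.
    Includes a synthetic Notch-like sequence generator with planted ground
    truth so that every stage of the pipeline is verifiable without
    database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    Biostrings,
    jsonlite
Config/testthat/edition: 3
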