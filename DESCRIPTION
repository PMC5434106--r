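Package: hcbprimer
Title: In Silico Evaluation of Universal 16S rRNA Gene Primer Pairs for
    Hydrocarbon-Degrading Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing how well universal bacterial 16S rRNA gene
    PCR primer pairs detect obligate hydrocarbonoclastic bacteria (HCB).
    Curates genus-validated reference sequences by dereplication, greedy
    97%-identity OTU clustering, template-based alignment and gap-column
    filtering; builds neighbor-joining trees with bootstrap support and
    applies a type-strain-anchored monophyly rule to validate genus
    membership; computes perfect-match coverage of IUPAC-degenerate primer
    pairs per taxon and amplicon size class; extracts in-silico amplicons
    and tests whether they are classified to the correct genus by a
    word-based naive Bayesian classifier with bootstrap confidence. A
    synthetic-sequence generator with a known truth table makes every stage
    testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
LinkingTo: Rcpp
RoxygenNote: 7.3.3
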