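Package: dtsb
Title: Decision Tree-Based SNP Barcoding for Species Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds minimal species-diagnostic SNP barcodes from a panel of
    aligned DNA barcode sequences (one representative per species, e.g. COI).
    A greedy binary decision tree is induced over alignment columns using a
    balance-and-diversity position score (with information gain and Gini
    index available as alternative split criteria); each root-to-leaf path
    yields an ordered set of (position, nucleotide) pairs that uniquely tags
    one species within the panel. Includes alignment trimming to the
    blunt-ended common region, per-site nucleotide distributions,
    combinatorial bounds on barcode length, a tree-walking classifier,
    barcode matching, seeded synthetic panel generators, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
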