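Package: pairForest
Title: Cell-Type-of-Origin Classification from Gene-Pair Rules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rank-based classification of the cell type of origin of bulk and
    pseudo-bulk RNA-seq samples. Binary gene-pair rules ("expression of gene A
    is less than expression of gene B within a sample") are generated from
    Random-Forest gene importance rankings, pruned with a shadow-feature
    (Boruta-style) test, and fed to a probability forest that emits per-class
    prediction scores. Because rules compare expression only within a sample,
    the classifier is invariant to any strictly monotone per-sample transform
    and therefore robust to cross-study batch effects. Includes a seeded
    synthetic-data generator (multi-study negative-binomial counts with
    cell-type marker structure, mixtures, and single-cell dropout), pseudo-bulk
    aggregation, stratified evaluation with exact binomial confidence
    intervals, and an alignment-free k-mer read-origin / rRNA-fraction module
    for library quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    ranger,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    caret,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
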