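Package: qgroupmap
Title: Read Mapping with the Succinct q-Group Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A filtration-plus-validation short-read mapper built on the
    q-group index, a rank-based succinct variant of the classical q-gram
    index that replaces the 4^q-word address table by an occurrence
    bit-vector with popcount-based rank lookups, shrinking the index up to
    16-fold when 4^q far exceeds the text length while keeping constant
    time per retrieved position. Reads are batched, 2-bit encoded and
    indexed; the reference is streamed against the batch index to produce
    candidate diagonals, which are verified with a banded bit-parallel
    (Myers) semi-global edit-distance computation and filtered by percent
    identity. Postprocessing groups hits into identity strata, pairs mates,
    assigns Bayesian PHRED-scaled mapping qualities and emits SAM. Includes
    a reference indexer with frequent-q-gram masking, a read/genome
    simulator with known truth, and truth-based sensitivity, recall and
    precision evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
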