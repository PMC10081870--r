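Package: dipwmscan
Title: Dinucleotide Position Weight Matrix Motif Search in DNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds occurrences of dinucleotide position weight matrices
    (di-PWMs), the HOCOMOCO-style motif model that scores the 16 dinucleotides
    at each pair of adjacent positions and thereby captures dependencies
    between neighboring motif positions. Implements an enumeration search
    strategy: valid words reaching a score threshold are enumerated by a
    branch-and-bound trie walk pruned with LookAhead/LookBack matrices,
    optionally restricted to a high-selectivity core interval of the matrix,
    then located in nucleotide sequences (including IUPAC ambiguity codes)
    with a constant-width dictionary matcher, and candidate windows are
    rescored against the full matrix. Also provides a lookahead-pruned window
    scanner, exact discretized score distributions under an i.i.d. background
    for P-value thresholds and per-occurrence P-value annotation, readers and
    writers for the di-PWM text format, FASTA, TSV and BED6 outputs, and a
    synthetic fixture generator with planted occurrences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
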