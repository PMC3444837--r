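Package: lwords
Title: Alignment-Free DNA Sequence Comparison via Suffix Trees and L-Word Frequencies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares sets of DNA sequences without alignment. A generalized
    suffix tree over all sequences is built in linear time by Ukkonen's
    algorithm (optionally depth-truncated) and used to count every word of a
    single automatically selected length L, the ceiling of the base-4
    logarithm of the longest sequence length. Per-sequence relative-frequency
    profiles over the 4^L possible words are compared by the standard
    Euclidean distance, and the resulting matrix feeds a neighbor-joining
    dendrogram or a classical multidimensional-scaling embedding. Includes a
    substitution-only sequence-evolution simulator for end-to-end validation
    and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    Biostrings,
    optparse,
    jsonlite
Config/testthat/edition: 3
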