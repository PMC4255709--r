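Package: cgisig
Title: Sequence Signals of CpG-Island Methylation State
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Relates CpG-island (CGI) DNA sequence to DNA-methylation state
    with permutation-based CpG-spacing periodicity tests built on
    dinucleotide-frequency-invariant (Eulerian-path) sequence shuffling,
    IUPAC motif presence/density statistics with shuffle and local-CpG-density
    controls, simplified discriminative motif discovery with a
    characteristic-motif (extreme-outlier) criterion, classification of CGIs
    relative to transcripts and active promoters, and multi-factor logistic
    deviance/interaction analysis of binary methylation predictors. Includes
    seed-deterministic synthetic-data generators (Markov-chain CGI-like
    sequences, periodic CpG placement, logistic factor tables, genomic
    layouts) with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
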