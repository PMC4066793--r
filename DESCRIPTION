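Package: shiftscan
Title: Detection and Statistical Analysis of Bacterial -1 Ribosomal
    Frameshifting Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying programmed -1 ribosomal frameshifting
    (PRF-1) signals in bacterial coding sequences. Enumerates and scans
    the slippery tetramer (Z_ZZN) and heptamer (X_XXZ_ZZN) motif
    universe in all three codon phases, builds a constrained
    randomization null model (dicodon shuffling that exactly preserves
    the encoded protein, codon usage and dinucleotide composition) with
    per-motif z-scores, clusters candidate genes and applies an
    N1/N2/N3 motif-conservation filter, detects upstream
    Shine-Dalgarno-like and downstream RNA hairpin stimulators with
    empirical energetic rules backed by a minimum-free-energy folding
    engine, converts reporter-assay activity tables into frameshift
    percentages with a motif/no-motif ratio classifier, and provides
    seed-deterministic synthetic-data generators so that the entire
    pipeline can be exercised end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
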