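Package: minicircle
Title: Mitochondrial Minicircle Reconstruction and Heteroplasmy Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs small circular mitochondrial minichromosomes from
    an internal gene sequence and an outward-facing amplicon, annotates them
    (protein gene, tRNA, inverted repeats, conserved blocks, noncoding
    spans), and quantifies heteroplasmy from sets of cloned amplicon
    sequences mapped to the reconstructed circle. Includes circular
    coordinate arithmetic, translation under the invertebrate mitochondrial
    genetic code with atypical start-codon classification, an affine-gap
    global aligner, an einverted-style inverted-repeat scanner, cross-species
    conserved-block discovery, neighbor-joining clone similarity trees, and a
    seeded simulator of minicircles and heteroplasmic clone sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
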