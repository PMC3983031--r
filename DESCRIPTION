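Package: cryptosplice
Title: Discovery and NMD Classification of Non-Productive Splicing from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering alternative splice-site usage in
    intron-containing genes of budding yeast from gapped RNA-seq alignments,
    classifying each splice product for premature termination codons (PTCs)
    and candidacy for nonsense-mediated mRNA decay (NMD), quantifying
    unspliced (intronic) signal, and testing enrichment of non-productive
    isoforms in NMD-deficient strains against wild type with Poisson
    statistics. Includes a toy-scale two-step spliced aligner (ungapped
    first, then single-gap), a synthetic-genome and read simulator with an
    explicit NMD decay model and full ground truth, and position-frequency
    matrix / information-content summaries of splice-site consensus
    sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
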