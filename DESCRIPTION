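Package: RRNPPminer
Title: Genome Mining of RRNPP Quorum-Sensing Regulator Repertoires
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects RRNPP-family quorum-sensing regulators (Rgg, ComR, PlcR,
    PrgX) in bacterial genomes with a single generic profile hidden Markov
    model built from a bait alignment, clusters the filtered hits into
    similarity clusters by connected components at an identity cutoff,
    discovers short coding sequences (7-60 aa) with a sequence-composition
    model and annotates candidate auto-inducing peptides (SHP, ComS, PapR,
    LCP, MutS) including predicted mature forms, and summarises regulator
    repertoires across strains (presence/absence matrices, profile diversity,
    hierarchical ordering, neighbor-joining trees with midpoint rooting).
    Peptide-chemistry utilities (Kyte-Doolittle GRAVY, monoisotopic masses,
    modification deltas, m/z, peak matching) support mass-spectrometry table
    construction. A synthetic-genome generator with a ground-truth manifest
    makes every stage testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    igraph,
    ape,
    phangorn,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
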