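Package: skewori
Title: Compositional Strand Asymmetry Indices for Replication Origin
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis and prediction of DNA replication origins from
    compositional strand asymmetries in compact eukaryotic genomes.
    Computes GC and TA skews over third codon positions, fourfold
    degenerate sites and intergenes; sliding-window and anchor-averaged
    skew profiles around oriented loci; four-segment asymmetry indices
    and the global index combining them; intergene scoring with ROC
    evaluation, top-rank enrichment tests and logistic combination of
    index components; origin calling from replication timing profiles
    with fractional interorigin binning and quasibinomial trend tests;
    an iterative codon adaptation index; and a synthetic genome
    generator with programmable replication- and transcription-
    associated skews for validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
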