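Package: intronevo
Title: Inference of Spliceosomal Intron Loss and Gain Across a Small Clade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics pipeline for studying the mechanisms of
    spliceosomal intron loss and gain. Builds validated gene models from
    genome FASTA and GFF3 annotation, detects one-to-one orthologs by
    reciprocal best hits, projects intron positions through protein-guided
    codon alignments, reconstructs presence/absence histories by Dollo
    parsimony on a fixed species tree, and characterises each inferred loss
    (precision, adjacency, boundary direct repeats, relative position,
    flanking GC content, four-fold-site GC). Inferential machinery includes
    a resampling null and an exact convolved null distribution for
    adjacent-loss clustering, plus candidate source-sequence filtering for
    putative intron gains. A synthetic-clade simulator with recorded ground
    truth makes every stage testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
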