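Package: itrtools
Title: Degenerate ITR Motif Scanning and Transposon-End Binding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping the 19-nt Hsmar1 inverted terminal repeat (ITR)
    core motif across a genome with up to three mismatches, classifying hits
    into MITE-like paired elements and solo ITRs, testing ChIP-peak enrichment
    over genomic features against blacklist-aware randomized interval nulls,
    relating ITR sequence fidelity to binding affinity from per-base coverage
    tracks, stratifying gene expression by ITR fidelity, and generating
    synthetic genomes, ChIP tracks and expression tables with known planted
    truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
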