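Package: footprintkit
Title: Phylogenetic Footprinting of Degenerate Transcription-Factor Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts direct transcription-factor gene targets by phylogenetic
    footprinting of degenerate binding motifs in promoter regions. Scans
    upstream sequences for IUPAC consensus patterns (the ASML1/WRI1 AW-box by
    default) on both strands, tests motif enrichment in gene sets and across
    orthologous upstream regions with the hypergeometric distribution and a
    shuffled-sequence empirical false discovery rate, calls cross-species
    conservation of extended motif sites, scores co-expression with a guide
    gene against a permutation null, builds log2-odds position weight matrices
    from binding-affinity data with ROC-based classification, and integrates
    all evidence layers into a multi-criteria target call. Includes a fully
    parameterised synthetic-data generator (ortholog catalogs with polyploidy,
    divergent upstream regions with planted sites, expression time courses,
    affinity tables) so every stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
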