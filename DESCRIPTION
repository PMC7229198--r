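Package: orthostage
Title: Cross-Species Orthologous-Metaexon Construction and Developmental
    Staging of Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for placing single-cell transcriptomes from
    one species onto the developmental axis of a reference embryo from
    another. Builds a high-confidence table of orthologous metaexons between
    two species from exon annotations and exon-versus-genome alignment hits
    (reciprocal mapping, identity and second-hit filters, gene-level
    chromosome and intron-size consistency checks); assigns aligned-read
    intervals to metaexons and genes; applies cell- and gene-level quality
    control and log2(CPM+1) normalization; harmonizes the two species by
    per-cell rank transformation and z-scoring; runs joint principal
    component analysis and assigns query cells to reference embryo stages in
    a selected component subspace; and summarizes stage-specific gene panels
    across cell groups. Ships a seeded synthetic-data generator (toy genomes
    with planted orthologs, decoy duplications and intron-size shifts;
    stage-structured two-species count matrices with monotone platform
    distortion, library-size variation and dropout) that exercises the whole
    pipeline against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
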