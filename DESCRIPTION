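Package: occuscape
Title: Co-Occupancy, Chromatin-State and Motif Analysis of Many ChIP-Seq Peak Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative analysis of large transcription-factor ChIP-seq peak
    compendia: bounded peak merging and binary occupancy matrices, principal
    component views of multi-factor loci, chromatin-state enrichment against
    GC- and repeat-matched null sequences, position weight matrix scanning with
    exact lattice p-values, motif concordance and offset analysis, co-binding
    networks, and detection of high-occupancy target (HOT) regions with
    subsampling motif-recovery curves. Includes a deterministic synthetic
    regulome generator with planted anchors, tethered factors and HOT loci that
    serves as ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    Biostrings,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph
Config/testthat/edition: 3
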