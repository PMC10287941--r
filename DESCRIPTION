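Package: triager
Title: Epigenetically Weighted Cell Clustering and Gene Program Parsing for Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transcriptionally distinct cell populations and their
    regulatory gene programs by exploiting broad H3K27me3 domains observed
    across consortium-scale epigenomic data. Computes a per-gene repressive
    tendency score (RTS) from H3K27me3 peak breadth at transcription start
    sites, transforms expression matrices into discordance scores, calls cell
    population peaks in a 2D embedding via an RTS-weighted kernel density
    estimate decomposed with superlevel-set DBSCAN, and groups ranked gene
    lists into functional modules with a Gaussian mixture model selected by
    BIC in H3K27me3 principal-component space. Includes benchmarking
    statistics (adjusted Rand index, ablation curves, Spearman peak
    correlation, rank-bin enrichment) and seed-deterministic synthetic data
    generators for closed-loop testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    mclust,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
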