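Package: chipxpr
Title: Integrative Analysis of Transcription Factor Occupancy and Knockout
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating transcription-factor ChIP-seq occupancy
    with knockout-versus-wildtype transcriptome profiling. Provides a
    local-lambda Poisson peak caller for tag libraries, basal-plus-extension
    regulatory domains for peak-to-gene assignment with TSS-distance binning,
    IUPAC consensus motif scanning with Z-score enrichment against sampled
    genomic background and two-motif module detection, a fold-change/p-value/
    above-background differential-expression filter, hypergeometric and
    contingency-table statistics for gene-set integration (bound, responsive
    and regulated gene sets), pre-ranked gene set enrichment analysis with a
    permutation null, and a seeded synthetic-data generator that plants
    peaks, motifs and expression effects with known ground truth so every
    stage of the pipeline can be benchmarked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
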