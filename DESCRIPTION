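Package: norfscan
Title: Novel Open Reading Frame Discovery and Regulatory-Region Association
    in Case-Control Brain Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies novel open reading frames (nORFs) transcribed and
    differentially expressed in case-control transcriptomes, associates them
    with human accelerated regions (HARs) and transposable elements (TEs),
    and tests their enrichment within disorder-associated GWAS loci.
    Implements Ribo-seq expression-noise filtering with quantile-binned
    canonical-ORF baselines, frame-relative ORF classification, intron-chain
    transcript matching, TMM/log-CPM normalization with per-transcript
    random-intercept mixed models, LD clumping and locus definition from
    GWAS summary statistics, and two-round permutation interval enrichment.
    A synthetic-data module generates every pipeline input with planted
    ground truth so the full workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    lme4,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
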