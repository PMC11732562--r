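Package: medipdmr
Title: Differential Promoter Methylation Analysis for MeDIP-Seq Two-Group Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A simulation-backed pipeline for calling differentially
    methylated promoters from MeDIP-seq (methylated DNA
    immunoprecipitation sequencing) read coordinates in a two-condition
    design, such as sedentary versus exercise-trained skeletal muscle.
    Provides regional methylation scoring by extended-read density
    (reads per kilobase) with three-state methylation status calls,
    TSS-anchored promoter and gene-body annotation, CpG-island detection
    under the Gardiner-Garden composition criteria, a fold-change plus
    P-value DMR filter cascade, pre-ranked gene-set enrichment and
    position-weight-matrix promoter scanning, and bisulfite
    pyrosequencing validation statistics (percent methylation,
    conversion QC, balanced two-way ANOVA and per-CpG tests). A
    synthetic-data generator with planted differential signal makes
    every stage testable against ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
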