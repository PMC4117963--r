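Package: medipmap
Title: MeDIP-Seq Methylome Profiling and Differential Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for MeDIP-seq (methylated-DNA immunoprecipitation
    sequencing) methylomes: four-criteria FASTQ quality filtering, sliding-window
    CpG-island detection (length/GC/observed-expected criteria), assignment of
    methylation peaks to genomic feature categories by a 50-percent-overlap rule,
    methylation-density statistics per feature and repeat class, gene-body
    metaprofiles, two-sample differentially-methylated-region (DMR) calling by
    2x2 chi-square with Benjamini-Hochberg FDR and fold-change selection, and
    TSS-centered k-means clustering of methylation signal. Includes a synthetic
    genome/methylome generator with planted CpG islands, feature-class peak
    densities and planted DMRs so the whole pipeline is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
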