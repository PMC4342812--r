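Package: radMethyl
Title: Radiation-Induced DNA Hypomethylation Screening and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovery and validation workflow for radiation-induced DNA
    hypomethylation from Illumina 450K-style beta-value methylation arrays.
    Calls differentially methylated probes against mock-treated controls using
    joint delta-beta and fold-ratio criteria, intersects irradiated contrasts
    with a 5-aza-2'-deoxycytidine demethylation control to nominate candidate
    genes, excludes pseudogenes and high-similarity paralogs, orders candidates
    by hierarchical clustering with Pearson-correlation similarity, and scores
    gene-level concordance with downstream assays: relative expression by the
    delta-delta-Ct method (GAPDH-normalized), quantitative methylation-specific
    PCR normalized to an Alu element, and DNMT1 promoter occupancy by ChIP-qPCR
    percent-of-input. A synthetic-data module generates array and Ct tables with
    planted effects so the full pipeline is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pheatmap
Config/testthat/edition: 3
RoxygenNote: 7.3.3
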