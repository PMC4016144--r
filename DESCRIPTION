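Package: triomix
Title: Parallel Comparison of Spectral-Count Proteomics, Two-Color
    Microarray and RNA-Seq Gene Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for comparing gene-level signals measured in
    parallel by three technologies on the same biological sample:
    label-free spectral counting of LC-MS/MS peptide-spectrum matches
    (with probability and target-decoy FDR filtering and protein-group
    expansion), two-color microarray intensities (background correction,
    within-array loess and between-array quantile normalization, and
    probe-to-gene collapse), and exon-overlap RNA-seq read counting.
    Detections are unified into a common gene namespace, partitioned into
    Venn regions, summarized per region, and compared by Spearman rank
    concordance under multi-gene-mapping and gene-category exclusion
    rules. A seeded synthetic tri-omics generator with a Gaussian-copula
    mRNA/protein dependence and built-in discordant gene categories
    (ribosomal, histone, vitellogenin) makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    limma,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Proteomics, Transcriptomics, Microarray, RNASeq, Normalization
RoxygenNote: 7.3.3
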