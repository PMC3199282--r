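Package: VulpesTx
Title: Transcriptome SNP Discovery and Two-Library Expression Comparison
    for Pyrosequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for transcriptome sequencing of a species
    without a reference genome, modelled on long-read pyrosequencing of
    brain cDNA from two individuals (one tame and one aggressive silver
    fox). Provides a 454-style read simulator with planted variants and
    expression truth; semiglobal read mapping with classification into
    fully/partially mapped, repeat, chimeric, too-short and unmapped
    categories; pileup-based discovery of single-nucleotide, indel and
    2-3 nucleotide differences with tiered minor-allele-fraction and
    read-depth filters, fixed-difference versus polymorphism
    partitioning, zygosity classification, X-chromosome heterozygosity
    filtering, cross-reference merging and synteny-based liftover;
    breadth-of-coverage, gene-yield saturation and per-base divergence
    statistics; and a two-proportion Z-test screen for expression
    differences between two non-normalized cDNA libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    BiocGenerics
Config/testthat/edition: 3
biocViews: Software, Sequencing, SNP, VariantDetection, Transcriptomics,
    GeneExpression, Coverage
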