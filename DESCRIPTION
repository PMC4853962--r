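Package: pathBLUP
Title: Genomic Mixed Models and LD-Preserving Pathway Association for
    Inbred Line Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative-genomic analysis of replicated
    phenotypes on panels of inbred, genome-sequenced lines such as the
    Drosophila Genetic Reference Panel. Implements the genomic
    relationship matrix from centred and scaled allele counts, REML
    estimation of SNP heritability under a GBLUP mixed model with
    bootstrap confidence intervals, back-solving of genome-ordered
    per-marker effects from line-level genomic values, a gene-ontology
    SNP-set association test whose null distribution is built by
    circular shifts of the marker-effect vector (preserving local
    linkage disequilibrium), cross-trait overlap testing of
    sub-threshold SNP-sets via incidence-matrix permutation, and
    partitioning of within-pathway genetic variance to genes. A
    synthetic-data generator emulating an inbred line panel with
    blockwise LD provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    GenomeInfoDb,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GenomeWideAssociation, SNP, Genetics, Pathways,
    StatisticalMethod
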