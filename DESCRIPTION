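Package: feqtl
Title: Kinship-Aware cis/trans eQTL Mapping for Feed-Efficiency Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end expression quantitative trait locus (eQTL) analysis
    pipeline for small, related livestock cohorts: minor-allele-frequency and
    linkage-disequilibrium tag-SNP filtering of genotype dosages, TMM
    normalisation and outlier filtering of RNA-seq counts, a pedigree-derived
    additive relationship matrix used as the error covariance of a generalized
    least squares all-pairs scan (linear-dosage and genotype-factor ANOVA
    models), genotype-permutation validation of the low-p-value excess,
    orthonormalized visualization coordinates, and surplus-based trans-eQTL
    category enrichment by Fisher's exact test. Includes a synthetic-data
    generator with planted cis/trans effects, covariate effects and pedigree
    relatedness so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
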