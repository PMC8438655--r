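Package: PopVarProfile
Title: Population-Genomic Profiling of Multi-Sample Variant Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Downstream population-genomic analysis of jointly called
    multi-sample VCFs from small captive cohorts, such as outbred rodent
    colony stocks. Provides GATK-style hard-filter evaluation on site
    metrics, per-sample SNP and indel counts and variant rates, 10-kb
    binned densities, functional-class (missense/nonsense/silent)
    summaries parsed from ANN effect annotations, indel length spectra
    and gene-region distributions, folded site frequency spectra with
    bucketed Watterson theta estimation, functional-class
    heterozygosity, an exact conditional Hardy-Weinberg test suited to
    detecting recessive-lethal loci, and pairwise polymorphism-sharing
    matrices with average-linkage clustering. A seeded two-population
    synthetic cohort generator with a machine-readable truth set makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    Biostrings,
    Rsamtools,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
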