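Package: popref
Title: Building Blocks for a Population Genome Reference from a Sequenced Cohort
Version: 0.1.0
Authors@R: person("popref", "developers", email = "popref@example.org", role = c("aut", "cre"))
Description: Cohort-level analyses used to construct and characterize a
    population genome reference: per-site allele statistics and major-allele
    calls from multi-sample genotypes, filtering of common cohort variants
    against external panel allele frequencies to obtain population-specific
    variants, GWAS tag-SNP selection and linkage-disequilibrium proxy
    comparison between two cohorts, calling of common non-reference insertion
    regions from per-base read-depth tracks, collapsing of overlapping
    structural-variant calls per individual, meta-assembly gap detection with
    patch extraction and base-level QV scoring, and summaries of phasing
    completeness and long runs of homozygosity. A synthetic-data module
    generates every input with the statistical structure the analyses assume,
    so the whole pipeline is testable without access-restricted cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
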