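Package: ReplicateConcordance
Title: Concordance Analysis of Variant Calls in Replicate Sequencing Experiments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the technical reproducibility of single nucleotide
    variant (SNV) calls between replicate sequencing experiments of the same
    genomic DNA. Implements pairwise and triplicate-averaged concordance rates
    over SNV calls and over all (unambiguous) nucleotide calls, stratified
    concordance by technical factors (coverage depth, variant allele count and
    frequency, variant allele quality, SNV-call p-value, substitution type,
    genome annotation, GC content) under a same-bin pairing rule with Sturges
    and empirical binning, factor-importance ranking by mutual information,
    univariate-logistic AIC and L1-penalized logistic entry order, and
    threshold-filter evaluation with before/after concordance testing. A
    seeded synthetic replicate-call generator with ground-truth labels makes
    every pipeline stage testable without access to restricted sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, SNP, VariantDetection, QualityControl, Coverage
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ReplicateConcordance-package.R'
    'methods-accessors.R'
    'binning.R'
    'association.R'
    'utils.R'
    'callset-io.R'
    'concordance.R'
    'filtering.R'
    'pipeline.R'
    'reference-counts.R'
    'simulate.R'
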