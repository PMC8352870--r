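Package: VariantVote
Title: Consensus Voting and Staged Prioritization of Pathogenic
    Missense Variants
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a consensus pathogenicity framework for
    nonsynonymous single-nucleotide polymorphisms (nsSNPs). Five
    functional-effect predictors (SIFT, PolyPhen-2, Condel, PROVEAN and
    PANTHER) are reduced to significant/not-significant calls under
    published thresholds and combined by k-of-5 voting models, optionally
    gated on evolutionary conservation and protein-stability evidence.
    A benchmarking harness computes sensitivity, specificity and accuracy
    against labeled standard sets, and a staged prioritization cascade
    (conservation, stability reliability, structural similarity,
    functional annotation) reduces candidate variants to a pathogenic
    shortlist with a full per-variant trace. Includes keyword-driven
    construction of cancer-variant datasets from GWAS-catalog-style
    tables, cohort VCF matching under read-depth and quality filters,
    packaged reference tables, and synthetic-data generators for
    benchmark records and VCFs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: VariantAnnotation, Classification, SNP, GenomicVariation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
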