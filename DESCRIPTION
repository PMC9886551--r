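Package: metapair
Title: Paired Primary-Metastasis Breast Tumor Multiomics Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a paired primary-metastasis
    breast cancer multiomics analysis pipeline. Provides the RNA-seq
    normalization chain (upper-quartile and median-of-ratios normalization,
    batch correction, normal-tissue contamination signature derivation and
    removal), signature and metagene scoring, receptor-status inference and
    PAM50 nearest-centroid subtyping with subgroup-specific gene centering,
    DNA-methylation beta-value screens for metastasis-associated hypo- and
    hypermethylation using purity-adjusted linear mixed models,
    transcription-factor binding-site enrichment, FFPE sequencing-artifact
    variant filters with mutation-frequency comparison, and copy-number
    segment scoring with HLA-locus focal-deletion calling. A synthetic
    paired-cohort generator with recorded ground truth makes every stage
    testable without access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    lme4,
    lmerTest,
    DESeq2,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, DNAMethylation, CopyNumberVariation,
    Transcriptomics, Epigenetics, Software
RoxygenNote: 7.3.3
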