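Package: vescatlas
Title: Multi-Tissue Expression Atlas and Structural-Variant Analytics for Woodland Strawberry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses a multi-tissue TPM expression atlas of the
    kind assembled for Fragaria vesca: tissue-specificity (tau) scoring and
    tissue-specific gene calling by a dual fold-change/FDR criterion,
    housekeeping-gene identification by a per-sample median-exceedance rule
    with stability ranking, batch-aware QC with cross-representation
    concordance metrics, and structural-variant analytics between two
    genome assemblies: multi-caller merging and confidence tiering,
    transposable-element content classification via a binomial-normal
    model, base-pair genic-overlap enrichment, promoter-window gene
    association, and SV-expression association tests. A deterministic
    synthetic-data generator emits every pipeline input with exported
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    limma,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
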