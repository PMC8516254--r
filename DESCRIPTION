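Package: hare
Title: Haplotype Associated RNA Expression for Transcriptome-Wide Genomic Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the cis haplotype associated component of RNA expression
    (HARE) in panels genotyped as founder-haplotype mosaics over genic
    reference ranges. Per-gene linear mixed models partition expression
    variance into a cis haplotype component, a genome-wide trans component and
    error by restricted maximum likelihood; per-haplotype expression effects
    (fixed-effect solutions or BLUPs) are extracted and can be imputed into
    any panel carrying the same founder haplotypes. Imputed HARE values serve
    as features for ridge-regression genomic prediction with within-panel and
    cross-panel evaluation protocols, benchmarked against a
    haplotype-structure-preserving permutation baseline with Monte Carlo
    p-values. Includes a simulator of nested association mapping (NAM) style
    biparental RIL panels and diverse mosaic panels with multi-tissue
    expression, so the full workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rtracklayer,
    vcfR
Config/testthat/edition: 3
biocViews: GenomicPrediction, GeneExpression, Genetics, Regression
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'methods.R'
    'ridge.R'
    'evaluate.R'
    'hare-package.R'
    'relationship.R'
    'varcomp.R'
    'hare.R'
    'io.R'
    'permtest.R'
    'popsim.R'
    'pipeline.R'
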