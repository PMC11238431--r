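Package: triplimeth
Title: Comparative Epigenomics of Duplicated Plant Genomes: DMR Calling,
    Breakpoint Methylation, Duplicate-Gene Classes and m6A Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream comparative-epigenomics analyses for plant genomes
    that carry an ancient whole-genome triplication: sliding-window calling of
    differentially methylated regions from bisulfite cytosine reports (ANOVA
    across replicate window levels, Benjamini-Hochberg FDR, context-specific
    effect-size cutoffs), methylation metaprofiles around genes, transposable
    elements and structural-variant breakpoints, presence/absence-variant
    boundary enrichment, syntenic collinear-block chaining with five-way
    duplicate-gene classification and 2-/3-copy grouping, and consensus
    N6-methyladenosine site summarisation with DRACH-motif and metagene
    analysis. Includes an exact small-sample Wilcoxon kernel and a seeded
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    stats,
    utils,
    methods,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
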