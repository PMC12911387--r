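Package: DefComTools
Title: Strain-Resolved Analysis of Defined Bacterial Communities in Plant
    Root Compartments
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for strain-resolved colonization analysis of defined
    bacterial communities (DefComs) sampled from plant root compartments.
    Provides a synthetic community generator with recorded ground truth,
    k-mer based average nucleotide identity (ANI) estimation and
    single-linkage lineage clustering, competitive read assignment to
    member genomes under unique or fractional multi-mapping policies,
    strain- gene- and orthogroup-level count matrices with CPM and TMM
    normalization, voom-style precision-weighted moderated t statistics
    for compartment contrasts, a lineage-level KEGG Ortholog enrichment
    rule, orthogroup diversity statistics (richness, Shannon,
    Bray-Curtis, NMDS, PERMANOVA), and a three-method consensus
    differential-abundance framework (negative-binomial Wald, voom
    moderated t, CSS normalization with zero-inflation weighting).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    vegan,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
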