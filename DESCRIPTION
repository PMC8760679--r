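Package: reactcap
Title: Predicted Metabolic Reaction Capacity of Gut Microbiota from 16S ASV Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the metabolic capacity of a gut microbial community from
    a 16S rRNA amplicon sequence variant (ASV) count table by matching ASVs to
    genome-scale metabolic models (GSMMs) at the lowest available taxonomic
    rank (species, genus, or family), building a reaction-expectation matrix,
    and computing abundance-weighted normalized reaction abundances per sample.
    Provides pairwise differential-reaction testing with Benjamini-Hochberg
    correction, Fisher's exact pathway (subsystem) enrichment, PCA ordination
    of standardized ASV and reaction profiles, and the community summaries
    used alongside such analyses: relative-abundance aggregation, core
    microbiota at a prevalence threshold, shared-ASV overlap between sample
    types, rarefaction, and alpha diversity (observed ASVs, Shannon, Pielou,
    Faith's phylogenetic diversity). Includes a Dirichlet-multinomial
    community simulator with planted compositional shifts and an analytic
    ground-truth oracle so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    picante,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
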