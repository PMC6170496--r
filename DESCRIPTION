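Package: methTAR
Title: Transgenerational Methylome Analysis for Acquired Disease Resistance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome bisulfite sequencing studies of
    transgenerational acquired resistance (TAR) in plants. Reads Bismark-style
    per-cytosine count tables, filters, normalises, destrands and unites them into
    analysis-ready matrices; calls differentially methylated positions with a
    beta-binomial Wald test using dispersion shrinkage (logistic-regression backend
    included) and segments differentially methylated regions; clusters samples by
    Pearson correlation and Ward linkage with multiscale-bootstrap AU/BP edge
    support; performs direction-aware shared-DMP set algebra, dose-intensity
    comparison, DMP-removal re-clustering and methylation-lability overlap tests;
    annotates positions against transposon/gene/intergenic features; and scores
    pathogen colonisation class tables with exact tests. A pedigree-structured
    methylome simulator with heritable epimutation and dose-dependent stress
    effects makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
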