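Package: aptapanel
Title: Aptamer Pool Profiling for Biomarker Panel Selection and Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of sequenced aptamer pools for plasma
    proteome profiling: collapse primer-flanked reads to a samples-by-aptamers
    count matrix, rank aptamers by abundance and filter to the most abundant
    set, select discriminative aptamer panels by per-aptamer ordinary least
    squares regression with Benjamini-Hochberg correction, score samples by
    the panel's first principal component with DeLong confidence intervals on
    the AUC, group aptamers into sequence-motif families, and assign each
    aptamer family a most probable protein target from mass-spectrometry
    pull-down intensities. Includes a synthetic-cohort generator with planted
    ground truth (aptamer families, negative-binomial counts, group effects,
    clinical covariates, pull-down intensity tables) so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
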