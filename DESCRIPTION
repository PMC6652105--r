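Package: chemcis
Title: Chem-Seq Peak Calling and Cis-Regulatory Analysis of Small-Molecule
    Chromatin Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for genome-wide localization of a biotinylated
    small molecule (quercetin) on chromatin. Implements a control-subtracted
    sliding-window Poisson peak caller with two scoring modes, two-caller
    consensus and streptavidin-bead background exclusion, promoter (TSS)
    association of peaks, gene-set and position-weight-matrix motif
    enrichment, median-of-ratios RNA-seq normalization with per-gene fold
    changes, and a cycle-structured permutation scheme that contrasts
    Kolmogorov-Smirnov p-values of an empirical gene set against random
    gene sets. Ships a synthetic-data generator with planted ground truth
    (binding sites, sticky bead regions, regulated genes) so the whole
    pipeline is exercised end-to-end without external data, plus a
    molecular-formula monoisotopic mass utility for electrospray adduct
    verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    withr,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
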