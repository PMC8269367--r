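Package: quadcoloc
Title: Colocalization Statistics for G-Quadruplexes and Chromatin Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for asking whether DNA G-quadruplexes
    (G4s) and i-motifs colocalize with protein-bound sites in the genome, and
    for quantifying the in vitro binding that would explain such
    colocalization.  Provides a consensus-pattern G4/i-motif sequence scanner;
    genomic interval-set operations (overlap counting, flank classification,
    base-pair coverage, relative-distance distributions, metaplot profiles,
    Venn counts); association statistics (Pearson chi-squared, two-sided
    Fisher exact by hypergeometric enumeration, a genome-wide Fisher table
    construction, and Monte-Carlo permutation tests with optional
    open-chromatin masks); per-CpG methylation aggregation over interval
    sets; a 1:1 titrant-depletion equilibrium binding (Kd) fitter for
    microscale-thermophoresis dose-response curves; and the delta-delta-Cq
    ChIP-qPCR occupancy computation.  A synthetic-data module generates toy
    genomes with planted motifs, enrichment-controlled interval sets,
    methylation tracks, binding curves and Cq tables with known ground truth,
    so the whole pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
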