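Package: th2axis
Title: Th2 Cytokine Receptor Co-Expression Screening and STAT Motif Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking Th2 cytokine (IL-4/IL-13) receptor
    heterodimer expression to tight-junction gene suppression in allergic
    rhinitis. Provides group-level cohort statistics (Livak 2^-ddCt relative
    quantification, Shapiro-Wilk-gated two-group tests, Pearson correlation
    with sample-size critical-r thresholds), a dual-subunit receptor
    co-correlation screen over expression matrices with probe-to-gene
    collapsing, hypergeometric gene-set over-representation with
    Benjamini-Hochberg FDR, and STAT consensus motif (TTC(N)2-4GAA) scanning
    over gene regions (5 kb upstream, first two introns, 5 kb downstream)
    with STAT6 compatibility calls. Includes seeded synthetic-data generators
    for expression matrices, cohort tables and genomes with planted motifs,
    each emitting ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
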