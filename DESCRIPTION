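Package: regulonforge
Title: GGAA-Microsatellite Peak Profiling, Direct-Target Calling and
    Cohort Screens for Fusion-Oncoprotein Regulomes
Version: 0.1.0
Authors@R:
    person("Regulonforge", "Developers", email = "regulonforge@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing genes repressed by ETS-family fusion
    oncoproteins (EWSR1::FLI1 / EWSR1::ERG) from standard genomics inputs:
    quantification of consecutive GGAA/TTCC microsatellite runs in windows
    around peak summits, strand-aware promoter/distal peak classification,
    repressive histone-mark (H3K9me3/H3K27me3) category assignment per locus,
    direct-target calling by intersecting binding with differential
    expression, tumor-cohort screens (Welch range test, correlation screen
    with Benjamini-Hochberg FDR, top-quartile/median concordance,
    Kaplan-Meier/log-rank), qPCR delta-delta-Ct fold changes, and cell
    motility track metrics. A synthetic-data module generates every input
    with ground-truth sidecars so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    survival,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
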