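Package: azadem
Title: Genome-Wide Analysis of DNA Demethylation by 5-aza-2'-deoxycytidine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantifying genome-wide DNA demethylation
    induced by the DNMT1 inhibitor 5-aza-2'-deoxycytidine (decitabine) and its
    downstream regulatory consequences. Implements global methylation scoring
    from luminometric methylation assay (LUMA) pyrosequencing runs, per-site
    HpaII/MspI angle scores from HELP-tagging count data, self-organizing-map
    compartmentalization of the genome from 100-kb window features, CG
    observed/expected promoter classification with a data-driven bimodal
    cutoff, k-means clustering of promoter methylation and expression
    trajectories across acute treatment and recovery, RNA-polymerase peak-set
    comparison with genic-context classification, and intronic retention
    scoring from exon/intron coverage. A synthetic-data generator produces a
    small two-compartment genome with planted effects so the full pipeline is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
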