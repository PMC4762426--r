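Package: stresscan
Title: Transcription Stress and DNA Damage Mapping from Paired-Condition
    Coverage Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies genes as suffering transcription stress (RNA
    polymerase II accumulation without a matching increase in nascent
    transcription) and DNA damage (elevated gamma-H2AX relative to histone
    H3) from paired-condition ChIP-seq and GRO-seq coverage tracks.
    Quantifies per-gene densities over gene-body windows, builds
    case:control ratio tables and Z-scores, computes promoter-anchored and
    scaled-gene-body metagene profiles, ranks genes into top-decile damage
    and stress sets, tests gene-set overlap and enrichment (hypergeometric,
    rank-based Kolmogorov-Smirnov, location tests), and tests de novo
    mutation burden in targeted panels against a binomial expectation from
    a per-site mutation rate over a number of cell generations. Ships a
    fully specified synthetic-data generator with truth tables so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
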