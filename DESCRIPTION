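Package: chiprx
Title: Spike-In Normalized (ChIP-Rx) Analysis of ChIP-Seq Experiments
Version: 0.1.0
Authors@R: person("chiprx", "maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative ChIP-seq analysis with an exogenous spike-in
    reference genome (ChIP-Rx). Computes input-corrected spike-in scaling
    factors, strand-resolved scaled coverage tracks in bedGraph form,
    average coverage profiles around transcription start sites, broad peak
    calls from a sliding-window Poisson test, and head-to-head comparisons
    of reads-per-million versus spike-in normalization. Includes a seeded
    synthetic-data generator that emulates a two-species chromatin mixture
    (target cells plus insect spike-in cells) so the whole pipeline is
    testable as a parameter-recovery experiment without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
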