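Package: callingcardr
Title: Transposon Calling Cards Analysis of Replication-Protein Chromatin Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses transposon "calling cards" sequencing
    experiments, in which a chromatin-bound protein fused to the Sir4
    integrase-tethering domain directs Ty5 retrotransposon integrations that
    permanently mark its binding sites. The package generates synthetic
    genomes, feature annotations, replication-timing landscapes and
    junction-read libraries under a restriction-digest, circularisation and
    inverse-PCR read model; calls deduplicated insertion events from junction
    reads with an exact both-strand mapper or from externally aligned SAM/BAM;
    normalises events into reads-per-million and unique-insertion signal
    tracks; and computes replication-timing window statistics and
    feature-centred meta-profiles (ARS consensus sites, Orc1 sites,
    centromeres, TSS) with exact Wilcoxon rank-sum comparisons and
    transposition-efficiency estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    methods,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
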