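Package: meiodsrna
Title: Detecting Programmed Double-Stranded RNA Formation Across Meiosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational screen for programmed double-stranded RNA (dsRNA)
    formation during synchronized yeast meiosis. Quantifies per-transcript
    structural remodeling from time-resolved chemical-probing (DMS) reactivity
    profiles and screens for unidirectional reactivity loss, the signature of
    intermolecular sense-antisense duplex formation; computes strand-specific
    antisense read-ratio dynamics, selects dynamic genes, assigns antisense
    activation intervals and clusters trajectories with centroid linkage on
    centered Pearson correlation; scans antisense-promoter regions for URS1 and
    MSE cis-elements, maps transcription-initiation clusters from strand-tagged
    read 5' ends and links motifs to antisense TSSs; detects pulsed sense
    expression and annotates sequentially convergent promoters. A synthetic-data
    generator emulates the statistical structure of all inputs with ground-truth
    labels for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    tidyr,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
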