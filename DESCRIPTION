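Package: assayqc
Title: Validation and Run Quality Control for Somatic Hotspot Sequencing Panels
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analytical validation and routine quality control of
    amplicon-based somatic variant panels. Predicts expected variant allele
    frequencies for weighted cell-line mixtures and serial dilutions with
    copy-number-aware locus handling, estimates the limit of detection from
    replicate dilution series, derives run-acceptance cutoffs from historical
    metric distributions (Shapiro-Wilk normality gate, optional log10
    transform, z-score bounds), scores concordance against orthogonal
    single-gene assays, flags recurrent artifact variants (high-MAF SNPs,
    amplicon-edge and homopolymer errors), and monitors an FFPE quality-control
    material across runs with Levey-Jennings control charts and optional
    Westgard multi-rules. A seeded binomial read-count simulator generates
    synthetic profiles, runs, dilution series and drift scenarios so every
    stage can be exercised without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    vcfR,
    rtracklayer,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
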