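Package: csmfr
Title: Detection of Group-Exclusive Somatic Mutation Cluster Regions in Cohort Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A pipeline for the analysis of blood somatic single-base
    substitutions (SSBS) in a two-group cohort design (centenarians versus
    younger controls): dual-caller consensus and eight-criterion variant
    filtering, detection of mutation clusters by genomic distance and their
    classification into group-exclusive region classes (CSM-FRs and CSM-CRs),
    randomized-region permutation tests and Fisher's exact tests of functional
    enrichment, per-sample burden and deleteriousness statistics with
    trinucleotide mutational spectra, and robustness checks
    (distance-threshold sensitivity, leave-one-out recall, sample-exclusion
    persistence). Includes a synthetic two-group cohort simulator with planted
    group-exclusive clusters and matching annotation tracks so every stage is
    testable without access to restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
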