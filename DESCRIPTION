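Package: liquidpanel
Title: Targeted-Panel Liquid-Biopsy Analysis for Neuroblastoma ctDNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for circulating tumour DNA (ctDNA) sequenced
    with a targeted UMI gene panel, built around neuroblastoma liquid
    biopsies. Implements a stringent somatic variant filtering cascade
    (depth, allele frequency, population germline and matched-germline
    subtraction), pathogenicity tiering from SIFT, PolyPhen-2, REVEL and
    COSMIC evidence, per-target coverage z-score detection of oncogene
    amplification with a trimmed baseline, longitudinal and cross-compartment
    variant concordance with tumour-purity estimation from allele
    frequencies, and Poisson quantification of droplet digital PCR counts.
    A synthetic-data generator produces panel datasets with known ground
    truth so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
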