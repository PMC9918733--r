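Package: scamp
Title: Analysis of Targeted Single-Nucleus Amplicon DNA Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of droplet-based targeted single-nucleus DNA
    sequencing (snDNA-seq) of solid tumors. Starting from per-barcode
    depth/alternate-read count matrices and per-amplicon read counts, the
    package calls complete cells from raw barcodes, assigns per-cell SNV
    genotypes with depth, allele-frequency and alternate-read thresholds,
    derives de-novo high-quality variant lists, estimates allelic dropout
    from germline heterozygous SNPs, infers droplet doublet rates from
    two-population mixing experiments via a genotype mixture model, computes
    per-amplicon ploidy against a diploid baseline to detect homozygous
    deletions, and performs driver-based clonal analysis. A clone-structured
    synthetic data generator with known ground truth supports validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
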