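Package: imprintscan
Title: Discovery of H3K27me3-Dependent Genomic Imprinting from
    Allele-Resolved Multi-Omic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an integrated pipeline for discovering
    DNA-methylation-independent (H3K27me3-dependent) genomic imprinting
    from allele-resolved chromatin accessibility (liDNase-seq), nascent
    transcription (ERCC spike-in normalised RNA-seq against
    alpha-amanitin controls), gamete DNA methylomes (WGBS) and allelic
    H3K27me3 ChIP-seq. Provides SNP-based parental read assignment,
    allele-specific DNase I hypersensitive site classification, an
    exact negative-binomial test for nascent transcription, germline
    DMR and methylation-class calling, allelic ChIP enrichment criteria,
    the candidate-gene integration cascade, demethylase-rescue and
    derepression analyses, and a synthetic multi-omic data generator
    with planted imprinting ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    IRanges,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
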