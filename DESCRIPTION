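Package: somaticpair
Title: Bayesian Detection of Somatic Variation in Matched Tumor/Normal
    Sequencing Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A beta-binomial Bayesian framework for the joint analysis of
    matched tumor/normal short-read sequencing data. Scores candidate somatic
    point mutations and small insertions/deletions, somatic loss of
    heterozygosity, allelic imbalance at heterozygous sites, and somatic
    structural variation from discordant mate pairs, all with a shared
    conjugate beta-binomial evidence model that uses the normal-genome pileup
    to update the expected variant-evidence proportion. Includes a synthetic
    paired-sample generator and evaluation harness for coverage and
    tumor-purity experiments, a BAM-backed locus walker, and VCF output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    S4Vectors
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
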