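Package: ycnvr
Title: Y Chromosome Copy Number Variant Discovery and Haplogroup Enrichment
    from SNP Array Intensities
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and classification of copy number variants (CNVs) in the
    male-specific region of the human Y chromosome (MSY) from SNP-array log2
    ratio intensities.  Provides probe-to-region annotation against
    STS-delimited palindromes and amplicons, female-background probe
    exclusion, a transparent threshold-run segmentation caller with Bayesian
    breakpoint refinement, classification of per-region copy states against a
    catalog of named AZFc/palindrome CNV patterns, Y haplogroup assignment by
    phylogeny walking with exclusion-node naming and backmerging,
    haplogroup-by-carrier enrichment statistics (Pearson chi-square,
    likelihood-ratio G, Fisher exact with fixed-margin Monte Carlo, Pearson
    and adjusted residuals), correlation PCA of Y-SNP genotypes, and a
    synthetic cohort generator so the whole pipeline is testable without
    array data.
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
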