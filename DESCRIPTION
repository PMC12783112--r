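Package: gbsmap
Title: Genotyping-by-Sequencing SNP Calling and F1 Association Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reduced-representation (tunable
    genotyping-by-sequencing) SNP discovery and genotyping in biparental
    F1 populations, and for non-parametric association mapping of
    quantitative disease phenotypes such as fire blight percent lesion
    length. Implements read-support genotype calling with depth and
    fraction thresholds, per-site filters (call rate, allele number,
    genotype classes, minor allele frequency, heterozygosity bound),
    per-SNP allele-group Wilcoxon rank-sum scans with a Bonferroni
    genome-wide threshold and Manhattan plots, gene-annotation summary
    statistics with windowed density tracks, and a synthetic F1-cross
    generator (Haldane recombination, negative-binomial read depth,
    single-QTL phenotypes) so the whole analysis runs without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
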