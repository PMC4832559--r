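Package: lofscreen
Title: Loss-of-Function Variant Screening and Fertility Association in
    Candidate Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A pipeline for screening whole-genome sequence variants in
    candidate genes for high-impact (loss-of-function) consequences, with
    downstream validation statistics and genotype-phenotype association on
    estimated breeding values.  Implements a minimal transcript-model SNV
    consequence classifier (stop gained/lost, start lost, splice donor and
    acceptor disruption), a detection-panel filter cascade that retains
    novel variants whose homozygous-mutant genotype is absent, per-site
    population-genetic statistics (allele frequencies, observed
    heterozygosity, Hardy-Weinberg chi-square tests, expected
    mutant-homozygote counts, minor-allele-frequency groups), fixed-effect
    and identity-by-state kinship mixed-model association with Bonferroni
    correction, a three-class variant verdict, and a synthetic-data
    generator that emulates the full study design for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
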