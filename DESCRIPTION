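Package: splicedose
Title: Splicing Dysregulation and Drug-Sensitivity Analysis for Spliceosome-Mutant Leukemia Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the downstream consequences of spliceosome
    (SRSF2-class) hotspot mutations in leukemia cell models and primary
    samples. Implements Bayesian percent-spliced-in (PSI) estimation from
    junction read counts with Savage-Dickey Bayes-factor calling of
    differential cassette-exon inclusion; SSNG exonic-splicing-enhancer motif
    enrichment with positional metagene profiles and bootstrap confidence
    intervals; dose-response scoring (DMSO normalization, drug sensitivity
    scores, growth-rate-corrected GR metrics and GR50, four-parameter logistic
    IC50 fits) with the accompanying group-comparison statistics; and
    variant-allele-frequency based inference of mutant allele copy number.
    A seeded synthetic-data generator with planted ground truth makes every
    stage testable end to end.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
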