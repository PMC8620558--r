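Package: mitospectr
Title: Mutation Spectrum Analysis for Heteroplasmic Mitochondrial Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to quantify and characterise heteroplasmic mitochondrial
    DNA mutations from paired-tissue variant calls. Classifies variants as
    germline (shared between tissues of one animal) or somatic, computes
    per-sample mutation count and mutation frequency metrics genome-wide and
    by region, annotates substitution classes with reverse-complement
    collapsing, codon effects under the vertebrate mitochondrial genetic
    code, amino-acid property changes and frameshift status of indels,
    corrects strand-asymmetry spectra for nucleotide composition, computes
    circular rolling-window genome scans, and fits the associated paired
    tests, linear mixed models and ANOVA/Tukey comparisons. Includes a
    seeded synthetic-cohort generator emulating a mutator-mouse study design
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
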