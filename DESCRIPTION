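Package: tagarray
Title: Design and Evaluation of Population-Optimized Genotyping Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing and evaluating SNP genotyping arrays from a
    phased haplotype reference panel. Screens candidate variants with
    validation filters (dosage r-squared against a truth platform, Fst
    cross-platform drift, Hardy-Weinberg exact test, call rate, allele
    frequency), selects genome-wide tagging content with a greedy
    maximum-coverage algorithm over pairwise linkage disequilibrium plus
    functional (nonsynonymous/damaging) content modules, and evaluates a
    designed array by haplotype-copying imputation, IMPUTE-style info scores,
    imputation-based genomic coverage in allele-frequency strata and genomic
    windows, and duplicate/cross-platform concordance. Includes additive-model
    association scans with signal-selection and novelty rules for quantitative
    traits, and seed-deterministic synthetic-data generators (block-LD
    haplotype panels, population divergence, platform genotyping error,
    additive phenotypes) so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
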