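Package: sibexome
Title: Family-Based Exome Variant Prioritization and Case-Control Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease variants from whole-exome calls in a
    nuclear pedigree with an affected sibling pair, and analyzes follow-up
    case-control genotyping. Implements stepwise annotation-based variant
    reduction (functional class, segmental-duplication, and population allele
    frequency filters) with an auditable per-step count trace, detection of
    genomic segments where the affected sib pair is identical by descent on
    both haplotypes (a two-state hidden Markov model with Viterbi decoding),
    linkage-based and de-novo-based candidate set strategies, and a follow-up
    association toolkit: exact Hardy-Weinberg tests, genetic-model contingency
    tests, odds ratios with Woolf confidence intervals, max-statistic
    permutation adjustment, and analytic power for case-control designs. A
    seeded simulator generates Mendelian pedigree variant data (with
    recombination and genotype error) and case-control cohorts so the whole
    pipeline is testable without access to protected sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
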