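Package: snpswap
Title: Sample Swap and Mislabelling Detection from Targeted NGS SNP
    Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects sample handling errors (swaps, mislabels,
    cross-contamination) in targeted next-generation sequencing cohorts
    by genotyping a small panel of common single nucleotide polymorphisms
    directly from aligned reads and comparing all sample pairs by
    genotype concordance and variant-allele-fraction correlation.
    Includes a panel-selection pipeline that derives an informative,
    linkage-pruned SNP panel from accumulated cohort variant data, an
    expected-pair verifier for longitudinal samples, a subset-size
    sensitivity analysis, a contamination heuristic based on deviations
    from the diploid allele-fraction pattern, and a synthetic-cohort
    generator (Hardy-Weinberg genotypes, binomial read counts, planted
    handling errors, miniature BAM fixtures) so the whole workflow can
    be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    IRanges,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
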