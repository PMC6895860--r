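Package: finearray
Title: Content Selection for Custom Fine-Mapping Genotyping Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds the custom-content variant list for a fine-mapping
    genotyping array from index association signals, multi-ethnic
    replication summary statistics, reference genotype panels, variant
    annotations and a base-array manifest. Implements a two-arm filter
    cascade: a coding/regulatory arm (population frequency gate plus
    effect-class, CADD and RegulomeDB criteria) and a linkage
    disequilibrium arm whose per-signal r-squared requirement is
    conditional on replication status in Hispanic and African American
    samples. Pairwise r-squared is computed from phased haplotypes by
    direct counting or from unphased genotypes by EM estimation of
    two-locus haplotype frequencies. Final assembly applies designability
    filtering, imputation INFO-score pruning against a bead-type budget,
    and Infinium bead-type accounting, with a per-stage funnel report.
    Includes a synthetic-fixture generator that plants known LD structure
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    vcfR,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    IRanges,
    jsonlite,
    optparse
Config/testthat/edition: 3
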