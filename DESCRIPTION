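Package: splicemap
Title: Mapping and Characterising Splicing Quantitative Trait Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for genome-wide cis splicing QTL
    (sQTL) analysis: additive linear-model association between SNP dosages
    and percent-spliced-in (PSI) of alternative-splicing events within a
    +/-100 kb window, a two-layer "double correction" for multiple testing
    (Benjamini-Hochberg across all pairs, then a per-SNP local Bonferroni
    over the number of nearby events), LD-based pruning, construction of
    MAF-matched non-sQTL control sets, Fisher-exact enrichment of sQTL SNPs
    in functional classes, regulatory-element tracks and disease-associated
    GWAS loci, and credible-set triage of candidate risk genes. Includes a
    synthetic-data generator with block-LD genotypes and planted cis
    effects so the full pipeline is testable without restricted data.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
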