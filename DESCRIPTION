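Package: indelpop
Title: Forensic Population Genetics of Biallelic Insertion-Deletion Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the population-genetic characterisation of forensic
    insertion-deletion (InDel/DIP) marker panels from diploid genotype tables
    or published per-locus summaries. Computes allele frequencies, observed
    and Nei unbiased expected heterozygosity, polymorphism information
    content, match probability, powers of discrimination and exclusion,
    typical paternity index, and their panel-level combined indexes;
    reconstructs integer genotype counts from published summary rows; tests
    Hardy-Weinberg equilibrium by Levene exact enumeration and Monte-Carlo
    allele re-pairing; tests pairwise linkage disequilibrium on unphased
    genotypes by EM haplotype-frequency estimation with likelihood-ratio
    permutation tests; estimates sample-bias-corrected (Nei-Chesser) FST per
    locus, pairwise and multi-population; builds neighbor-joining trees and
    SMACOF multidimensional-scaling ordinations from FST distance matrices;
    runs locus-by-locus AMOVA with permutation p-values; and provides seeded
    generators for Hardy-Weinberg, inbred and Balding-Nichols structured
    genotype data. Ships the published 30-locus DIPplex summary table for a
    Polish population sample (n = 631) as a worked reference panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
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
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
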