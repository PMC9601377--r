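#' Locus-by-locus analysis of molecular variance (AMOVA)
#'
#' One-level AMOVA on the allele identity/non-identity distance: for each
#' locus the total allelic variance is partitioned into an among-population
#' and a within-population component by the standard nested sums of squares
#' over the `2n` alleles, giving `phi_ST = among / (among + within)`.
#' Significance comes from permuting individuals (keeping their two alleles
#' together) across populations and recomputing `phi_ST`, with the add-one p
#' estimator. For unlinked biallelic loci this is equivalent to an
#' FST-based AMOVA.
#'
#' @param tbl Genotype tibble with a complete `population` column; at least
#'   two populations of at least two individuals each.
#' @param n_perm Number of label permutations per locus (default 1000).
#' @param seed Master seed; per-locus permutation streams derive from it.
#' @inheritParams write_genotypes
#' @return Tibble with one row per locus: `locus`, `n`, `sigma_among`,
#'   `sigma_within`, `phi_st`, `p_perm`, `df_among`, `df_within`, `n_perm`,
#'   `seed`. The among component may be negative (its estimator is
#'   unbiased); the within component is non-negative.
#' @export
amova <- function(tbl, n_perm = 1000L, seed = 1L, sep = "/", missing = "./.") {
  validate_genotypes(tbl, sep = sep, missing = missing)
  abort_if(!"population" %in% names(tbl) || anyNA(tbl$population),
           "amova needs a complete 'population' column")
  abort_if(n_perm < 1, "n_perm must be >= 1")
  grp_all <- as.character(tbl$population)
  sizes <- table(grp_all)
  abort_if(length(sizes) < 2, "need at least two populations")
  abort_if(any(sizes < 2), "every population needs at least two individuals")
  loci <- locus_columns(tbl)
  purrr::map_dfr(seq_along(loci), function(li) {
    loc <- loci[li]
    calls <- tbl[[loc]]
    keep <- !is.na(calls)
    amova_one(loc, calls[keep], grp_all[keep], n_perm,
              derive_seed(seed, li), sep)
  })
}

amova_one <- function(locus, calls, grp, n_perm, seed, sep) {
  parts <- strsplit(calls, sep, fixed = TRUE)
  alleles <- sort_alleles(unique(unlist(parts, use.names = FALSE)))
  k <- length(alleles)
  n <- length(calls)
  # per-individual allele-count rows; group sums then give allele counts
  ac <- matrix(0L, n, k)
  for (j in 1:2) {
    aj <- match(vapply(parts, `[[`, "", j), alleles)
    ac[cbind(seq_len(n), aj)] <- ac[cbind(seq_len(n), aj)] + 1L
  }
  obs <- amova_phi(ac, grp)
  phi_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) amova_phi(ac, sample(grp))["phi"], numeric(1))
  })
  p <- (1 + sum(phi_perm >= obs[["phi"]] - 1e-12)) / (n_perm + 1)
  g_sizes <- table(grp)
  tibble::tibble(locus = locus, n = n,
                 sigma_among = obs[["sigma_a"]], sigma_within = obs[["sigma_w"]],
                 phi_st = obs[["phi"]], p_perm = p,
                 df_among = length(g_sizes) - 1L,
                 df_within = as.integer(2 * n - length(g_sizes)),
                 n_perm = as.integer(n_perm), seed = as.integer(seed))
}

# variance components from an individuals x alleles count matrix and a
# grouping vector; distances between alleles are 0/1 identity
amova_phi <- function(ac, grp) {
  gc <- rowsum(ac, grp)              # groups x alleles allele counts
  Ng <- rowSums(gc)                  # alleles per group (2 * individuals)
  N <- sum(Ng)
  G <- nrow(gc)
  p_tot <- colSums(gc) / N
  ssd_t <- N * (1 - sum(p_tot^2)) / 2
  ssd_w <- sum(Ng * (1 - rowSums((gc / Ng)^2)) / 2)
  ssd_a <- ssd_t - ssd_w
  ms_a <- ssd_a / (G - 1)
  ms_w <- ssd_w / (N - G)
  n0 <- (N - sum(Ng^2) / N) / (G - 1)
  sigma_a <- (ms_a - ms_w) / n0
  sigma_w <- ms_w
  c(sigma_a = sigma_a, sigma_w = sigma_w,
    phi = if (sigma_a + sigma_w > 0) sigma_a / (sigma_a + sigma_w) else 0)
}
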