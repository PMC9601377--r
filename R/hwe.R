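#' Levene conditional distribution of the heterozygote count
#'
#' Under Hardy-Weinberg equilibrium, conditional on the allele counts
#' (`n_a` copies of one allele among the `2n` in the sample), the number of
#' heterozygotes `h` follows the Levene/Haldane distribution
#' `P(h) = n! 2^h n_a! n_b! / (n_aa! h! n_bb! (2n)!)` over all `h` with the
#' parity of `n_a` and `0 <= h <= min(n_a, 2n - n_a)`.
#'
#' @param n_a Count of one allele among the `2n` alleles.
#' @param n Number of diploid individuals.
#' @return A tibble with the admissible heterozygote counts `h` and their
#'   conditional probabilities `prob` (summing to 1).
#' @export
levene_het_pmf <- function(n_a, n) {
  abort_if(n < 1 || n_a < 0 || n_a > 2 * n, "need 0 <= n_a <= 2n, n >= 1")
  n_b <- 2 * n - n_a
  h <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  logp <- lfactorial(n) - lfactorial((n_a - h) / 2) - lfactorial(h) -
    lfactorial((n_b - h) / 2) + h * log(2) +
    lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  tibble::tibble(h = h, prob = p / sum(p))
}

#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' Two-sided exact p-value by probability-mass ordering: the sum of Levene
#' conditional probabilities of every heterozygote count no more probable
#' than the observed one, given the allele counts. Monomorphic loci return 1
#' by convention (a single admissible outcome).
#'
#' @param n_dd,n_di,n_ii Genotype counts for the two homozygote classes and
#'   the heterozygote class.
#' @return Exact p-value in `[0, 1]`.
#' @examples
#' hwe_exact_p(153, 288, 190)
#' @export
hwe_exact_p <- function(n_dd, n_di, n_ii) {
  abort_if(any(c(n_dd, n_di, n_ii) < 0), "genotype counts must be non-negative")
  n <- n_dd + n_di + n_ii
  abort_if(n < 1, "need n >= 1")
  n_a <- 2 * n_dd + n_di
  if (n_a == 0 || n_a == 2 * n) return(1)
  pmf <- levene_het_pmf(n_a, n)
  p_obs <- pmf$prob[pmf$h == n_di]
  min(1, sum(pmf$prob[pmf$prob <= p_obs * (1 + 1e-9)]))
}

#' Monte-Carlo Hardy-Weinberg test by allele re-pairing
#'
#' Pools the `2n` observed alleles and re-pairs them into `n` diploid
#' genotypes uniformly at random `n_perm` times; each permuted heterozygote
#' count is scored by its Levene conditional probability, and the p-value is
#' the add-one estimator `(1 + k) / (n_perm + 1)` where `k` counts
#' permutations whose probability is at most that of the observed count.
#' This is the permutation analogue of [hwe_exact_p()] and converges to it.
#'
#' @inheritParams hwe_exact_p
#' @param n_perm Number of random re-pairings (default 10000).
#' @param seed Integer seed; results are reproducible given it.
#' @return Monte-Carlo p-value in `(0, 1]`.
#' @export
hwe_permutation_p <- function(n_dd, n_di, n_ii, n_perm = 10000L, seed = 1L) {
  abort_if(n_perm < 1, "n_perm must be >= 1")
  n <- n_dd + n_di + n_ii
  abort_if(n < 1, "need n >= 1")
  n_a <- 2 * n_dd + n_di
  if (n_a == 0 || n_a == 2 * n) return(1)
  pmf <- levene_het_pmf(n_a, n)
  # probability lookup indexed by heterozygote count
  h_min <- pmf$h[1]
  prob_of <- function(h) pmf$prob[(h - h_min) / 2 + 1]
  p_obs <- prob_of(n_di)
  alleles <- rep(c(0L, 1L), times = c(n_a, 2 * n - n_a))
  odd <- seq(1L, 2L * n, by = 2L)
  even <- odd + 1L
  k <- withr::with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      x <- sample(alleles)
      prob_of(sum(x[odd] != x[even])) <= p_obs * (1 + 1e-9)
    }, logical(1)))
  })
  (k + 1) / (n_perm + 1)
}

#' Hardy-Weinberg tests across a panel of loci
#'
#' Applies the exact and/or Monte-Carlo HWE test to every locus of a
#' genotype-count table, with per-locus permutation streams derived from one
#' master seed.
#'
#' @param counts Tibble with columns `locus`, `n_dd`, `n_di`, `n_ii`
#'   ([count_genotypes()] / [reconstruct_counts()] output).
#' @param method `"exact"`, `"permutation"`, or `"both"` (default).
#' @inheritParams hwe_permutation_p
#' @return Tibble with columns `locus`, `p_exact` and/or `p_mc`, `n_perm`,
#'   `seed`.
#' @export
hwe_test <- function(counts, method = c("both", "exact", "permutation"),
                     n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  purrr::pmap_dfr(
    counts[c("locus", "n_dd", "n_di", "n_ii")],
    function(locus, n_dd, n_di, n_ii) {
      stream <- derive_seed(seed, match(locus, counts$locus))
      out <- tibble::tibble(locus = locus)
      if (method != "permutation") out$p_exact <- hwe_exact_p(n_dd, n_di, n_ii)
      if (method != "exact") {
        out$p_mc <- hwe_permutation_p(n_dd, n_di, n_ii, n_perm = n_perm, seed = stream)
        out$n_perm <- n_perm
        out$seed <- stream
      }
      out
    })
}
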