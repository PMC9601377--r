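#' Simulate Hardy-Weinberg genotypes at biallelic D/I loci
#'
#' Draws `n` diploid individuals at independent biallelic loci with genotype
#' probabilities `(p_del^2, 2 p_del p_ins, p_ins^2)`. Per-locus random
#' streams are derived from the master seed by a fixed counter scheme, so
#' results are bit-reproducible and independent of evaluation order.
#'
#' @param freqs Named numeric vector of insertion-allele frequencies, one
#'   per locus (names become locus column names), or a data frame with
#'   columns `locus` and `freq_ins` such as [load_dipplex_panel()].
#' @param n Number of individuals.
#' @param seed Integer master seed.
#' @param populations Optional vector of population labels, either length
#'   `n` (one per sample) or a short vector of region names split as evenly
#'   as possible across the sample.
#' @return A genotype tibble (`sample_id`, optional `population`, one D/I
#'   column per locus).
#' @examples
#' g <- simulate_hwe_genotypes(c(HLD77 = 0.5578, HLD45 = 0.5261), n = 100, seed = 7)
#' count_genotypes(g)
#' @export
simulate_hwe_genotypes <- function(freqs, n, seed = 1L, populations = NULL) {
  simulate_inbred_genotypes(freqs, n, fis = 0, seed = seed, populations = populations)
}

#' Simulate genotypes under inbreeding (nonzero FIS)
#'
#' Genotype probabilities `(p^2 + fis*p*q, 2pq(1 - fis), q^2 + fis*p*q)`
#' with `p` the deletion and `q` the insertion frequency; `fis = 0` reduces
#' to the Hardy-Weinberg generator.
#'
#' @inheritParams simulate_hwe_genotypes
#' @param fis Inbreeding coefficient in `[0, 1)`.
#' @return A genotype tibble.
#' @export
simulate_inbred_genotypes <- function(freqs, n, fis = 0, seed = 1L,
                                      populations = NULL) {
  freqs <- as_freq_vector(freqs)
  abort_if(n < 1, "n must be >= 1")
  abort_if(fis < 0 || fis >= 1, "fis must lie in [0, 1)")
  tbl <- tibble::tibble(sample_id = sprintf("S%04d", seq_len(n)))
  if (!is.null(populations)) tbl$population <- expand_populations(populations, n)
  cols <- purrr::imap(freqs, function(q, loc) {
    p <- 1 - q
    probs <- c(p^2 + fis * p * q, 2 * p * q * (1 - fis), q^2 + fis * p * q)
    withr::with_seed(derive_seed(seed, match(loc, names(freqs))),
                     sample(c("D/D", "D/I", "I/I"), n, replace = TRUE, prob = probs))
  })
  dplyr::bind_cols(tbl, tibble::as_tibble(cols))
}

#' Simulate differentiated populations under the Balding-Nichols model
#'
#' For each population and locus the insertion-allele frequency is drawn
#' from `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` around the ancestral
#' frequency `p`, with `F` the target FST; genotypes are then drawn under
#' Hardy-Weinberg within each population. The Beta variance is
#' `F p (1 - p)`, so across-population expected heterozygosity is reduced
#' by the factor `(1 - F)` relative to the ancestral `2pq`.
#'
#' @param ancestral Named numeric vector of ancestral insertion-allele
#'   frequencies (or data frame with `locus` and `freq_ins`).
#' @param fst_target Differentiation parameter `F` in `(0, 1)`.
#' @param n_populations Number of populations.
#' @param sizes Per-population diploid sample sizes; recycled to
#'   `n_populations`.
#' @param seed Integer master seed.
#' @param pop_names Optional population labels (default `POP1`, `POP2`, ...).
#' @return A list with `frequencies` — the drawn per-population frequencies
#'   as a long tibble (`population`, `locus`, `allele`, `freq`, `n`) — and
#'   `genotypes`, a single genotype tibble with a `population` column.
#' @export
simulate_balding_nichols <- function(ancestral, fst_target, n_populations,
                                     sizes, seed = 1L, pop_names = NULL) {
  ancestral <- as_freq_vector(ancestral)
  abort_if(fst_target <= 0 || fst_target >= 1, "fst_target must lie in (0, 1)")
  abort_if(n_populations < 1, "need at least one population")
  sizes <- rep_len(sizes, n_populations)
  abort_if(any(sizes < 1), "population sizes must be >= 1")
  pop_names <- pop_names %||% sprintf("POP%d", seq_len(n_populations))
  fac <- (1 - fst_target) / fst_target
  freq_rows <- list()
  geno_tbls <- list()
  for (pi in seq_len(n_populations)) {
    q_pop <- vapply(seq_along(ancestral), function(li) {
      p <- ancestral[li]
      withr::with_seed(derive_seed(seed, pi * 10007L + li),
                       stats::rbeta(1, p * fac, (1 - p) * fac))
    }, numeric(1))
    names(q_pop) <- names(ancestral)
    freq_rows[[pi]] <- tibble::tibble(
      population = pop_names[pi],
      locus = rep(names(ancestral), each = 2),
      allele = rep(c("D", "I"), times = length(ancestral)),
      freq = as.vector(rbind(1 - q_pop, q_pop)),
      n = sizes[pi])
    g <- simulate_hwe_genotypes(q_pop, n = sizes[pi],
                                seed = derive_seed(seed, 900000L + pi))
    g$sample_id <- paste0(pop_names[pi], "_", g$sample_id)
    g <- dplyr::mutate(g, population = pop_names[pi], .after = "sample_id")
    geno_tbls[[pi]] <- g
  }
  list(frequencies = dplyr::bind_rows(freq_rows),
       genotypes = dplyr::bind_rows(geno_tbls))
}

#' Simulate a single multiallelic (STR-like) genotype column
#'
#' Hardy-Weinberg genotypes over `k >= 2` alleles; with two alleles it
#' matches the biallelic generator in distribution. Useful for mixed
#' STR x InDel linkage tests.
#'
#' @param freqs Named numeric vector of allele frequencies (names are the
#'   allele labels, e.g. repeat numbers).
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param sep Allele separator in emitted calls.
#' @return Character vector of `n` normalised genotype calls.
#' @export
simulate_multiallelic_locus <- function(freqs, n, seed = 1L, sep = "/") {
  abort_if(length(freqs) < 2, "need at least two alleles")
  check_freq_vector(freqs)
  abort_if(is.null(names(freqs)), "allele frequencies must be named by allele label")
  withr::with_seed(seed, {
    a1 <- sample(names(freqs), n, replace = TRUE, prob = freqs)
    a2 <- sample(names(freqs), n, replace = TRUE, prob = freqs)
    srt <- allele_pair_sorted(a1, a2)
    paste0(srt$first, sep, srt$second)
  })
}

#' Simulate a study-like reference panel
#'
#' Drop-in rehearsal of the reference dataset: Hardy-Weinberg genotypes at
#' the 30 DIPplex loci with the published Polish allele frequencies,
#' `n = 631` individuals split as evenly as possible across three region
#' labels (Poznan, Warsaw, Bialystok).
#'
#' @param seed Integer master seed.
#' @param n Number of individuals (default 631).
#' @param regions Region labels (default the three study regions).
#' @return A genotype tibble with a `population` column.
#' @export
simulate_reference_panel <- function(seed = 1L, n = 631L,
                                     regions = c("Poznan", "Warsaw", "Bialystok")) {
  panel <- load_dipplex_panel(verify = FALSE)
  simulate_hwe_genotypes(stats::setNames(panel$freq_ins, panel$locus),
                         n = n, seed = seed, populations = regions)
}

# ---- internals -------------------------------------------------------------

as_freq_vector <- function(freqs) {
  if (is.data.frame(freqs)) {
    abort_if(!all(c("locus", "freq_ins") %in% names(freqs)),
             "frequency data frame needs 'locus' and 'freq_ins' columns")
    freqs <- stats::setNames(freqs$freq_ins, freqs$locus)
  }
  abort_if(is.null(names(freqs)) || any(names(freqs) == ""),
           "locus frequencies must be named")
  abort_if(any(freqs < 0 | freqs > 1), "allele frequencies must lie in [0, 1]")
  freqs
}

expand_populations <- function(populations, n) {
  if (length(populations) == n) return(as.character(populations))
  sizes <- rep(n %/% length(populations), length(populations))
  sizes[seq_len(n %% length(populations))] <- sizes[seq_len(n %% length(populations))] + 1L
  rep(as.character(populations), times = sizes)
}
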