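#' Sample-bias-corrected FST between two populations
#'
#' Per-locus and multilocus FST using the Nei-Chesser (1983) unbiased
#' within- and total-heterozygosity estimators with the harmonic-mean sample
#' size, the computation behind "sample bias corrected" interpopulation
#' distances in population-tree software. Per locus,
#' `fst = 1 - Hs_hat / Ht_hat`; the multilocus value is the ratio of the
#' averaged estimators, `1 - mean(Hs_hat) / mean(Ht_hat)`. Observed
#' heterozygosity enters the correction at its Hardy-Weinberg expectation,
#' as appropriate for allele-frequency-only data. Small negative estimates
#' are retained here; they are clamped to zero only when a matrix is used as
#' a distance ([fst_matrix()]).
#'
#' @param freq_tbl Long-format frequency tibble (`population`, `locus`,
#'   `allele`, `freq`, `n`), e.g. from [population_frequencies()] or
#'   [read_frequency_table()].
#' @param pop_a,pop_b Population labels to compare.
#' @return An object of class `indel_fst`; `tidy()` gives the per-locus
#'   tibble (`locus`, `hs`, `ht`, `fst`), `glance()` the one-row multilocus
#'   summary.
#' @export
pairwise_fst <- function(freq_tbl, pop_a, pop_b) {
  pops <- unique(freq_tbl$population)
  abort_if(!all(c(pop_a, pop_b) %in% pops),
           "both populations must be present in the frequency table")
  sub <- dplyr::filter(freq_tbl, .data$population %in% c(pop_a, pop_b))
  per_locus <- fst_per_locus(sub, c(pop_a, pop_b))
  usable <- per_locus$ht > 0
  abort_if(!any(usable), "no polymorphic shared locus between the two populations")
  fst <- 1 - mean(per_locus$hs[usable]) / mean(per_locus$ht[usable])
  structure(list(populations = c(pop_a, pop_b), per_locus = per_locus, fst = fst),
            class = "indel_fst")
}

#' @export
print.indel_fst <- function(x, ...) {
  cat(sprintf("Nei-Chesser FST %s vs %s over %d loci: %.4f\n",
              x$populations[1], x$populations[2], nrow(x$per_locus), x$fst))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.indel_fst <- function(x, ...) x$per_locus

#' @exportS3Method generics::glance
glance.indel_fst <- function(x, ...) {
  tibble::tibble(pop_a = x$populations[1], pop_b = x$populations[2],
                 n_loci = nrow(x$per_locus), fst = x$fst)
}

#' Pairwise FST distance matrix over all populations
#'
#' @inheritParams pairwise_fst
#' @param clamp Clamp negative multilocus estimates to zero so the result is
#'   a valid distance matrix (default `TRUE`).
#' @return Symmetric matrix of multilocus pairwise FST with population
#'   labels, zero diagonal.
#' @export
fst_matrix <- function(freq_tbl, clamp = TRUE) {
  pops <- unique(freq_tbl$population)
  abort_if(length(pops) < 2, "need at least two populations")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in seq.int(i + 1, length(pops))) {
      f <- pairwise_fst(freq_tbl, pops[i], pops[j])$fst
      if (clamp) f <- max(f, 0)
      m[i, j] <- m[j, i] <- f
    }
  }
  m
}

#' Locus-specific FST across all populations
#'
#' Per-locus Nei-Chesser FST computed over every population in the table,
#' ranked most-differentiated first — the screen used to nominate
#' ancestry-informative markers (AIMs).
#'
#' @inheritParams pairwise_fst
#' @return Tibble `locus`, `hs`, `ht`, `fst`, `rank`, sorted by decreasing
#'   `fst`.
#' @export
locus_fst <- function(freq_tbl) {
  pops <- unique(freq_tbl$population)
  abort_if(length(pops) < 2, "need at least two populations")
  out <- fst_per_locus(freq_tbl, pops)
  out <- dplyr::arrange(out, dplyr::desc(.data$fst))
  out$rank <- seq_len(nrow(out))
  out
}

# ---- internals -------------------------------------------------------------

# Nei-Chesser unbiased Hs/Ht for one locus given a pops x alleles frequency
# matrix and per-population sample sizes (individuals).
nei_chesser_locus <- function(x, sizes) {
  s <- nrow(x)
  ntilde <- s / sum(1 / sizes)
  sum_x2 <- rowSums(x^2)
  ho <- mean(1 - sum_x2)  # HWE expectation of observed heterozygosity
  hs <- ntilde / (ntilde - 1) * (1 - mean(sum_x2) - ho / (2 * ntilde))
  xbar <- colMeans(x)
  ht <- 1 - sum(xbar^2) + hs / (ntilde * s) - ho / (2 * ntilde * s)
  c(hs = hs, ht = ht)
}

fst_per_locus <- function(freq_tbl, pops) {
  freq_tbl <- dplyr::filter(freq_tbl, .data$population %in% pops)
  shared <- dplyr::summarise(dplyr::group_by(freq_tbl, .data$locus),
                             n_pop = dplyr::n_distinct(.data$population))
  dropped <- shared$locus[shared$n_pop < length(pops)]
  if (length(dropped) > 0) {
    rlang::warn(paste0("dropping loci absent from some population(s): ",
                       paste(dropped, collapse = ", ")))
  }
  loci <- setdiff(shared$locus, dropped)
  abort_if(length(loci) == 0, "no locus shared by all populations")
  purrr::map_dfr(loci, function(loc) {
    sub <- dplyr::filter(freq_tbl, .data$locus == loc)
    alleles <- sort_alleles(unique(sub$allele))
    x <- matrix(0, length(pops), length(alleles), dimnames = list(pops, alleles))
    x[cbind(match(sub$population, pops), match(sub$allele, alleles))] <- sub$freq
    sizes <- vapply(pops, function(p) sub$n[match(p, sub$population)], numeric(1))
    est <- nei_chesser_locus(x, sizes)
    tibble::tibble(locus = loc, hs = est[["hs"]], ht = est[["ht"]],
                   fst = ifelse(est[["ht"]] > 0, 1 - est[["hs"]] / est[["ht"]], NA_real_))
  })
}
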