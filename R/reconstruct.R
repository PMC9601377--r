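#' Reconstruct integer genotype counts from published per-locus summaries
#'
#' A published summary row for a biallelic locus (allele frequencies rounded
#' to 4 decimals, observed heterozygosity, sample size n) determines the
#' underlying integer genotype counts essentially uniquely: the heterozygote
#' count is the nearest integer to `het_obs * n`, the insertion-allele count
#' the nearest integer to `freq_ins * 2n`, and the homozygote counts follow
#' by subtraction. Recomputed frequencies must agree with the printed inputs
#' within `tol`; otherwise (or if the implied insertion-homozygote count is
#' non-integral or any count negative) the row is inconsistent and the error
#' reports the closest integer solution and its residual.
#'
#' @param summaries Tibble with columns `locus`, `freq_ins` (or `freq_del`),
#'   `het_obs`, `n`. [load_dipplex_panel()] output works directly.
#' @param tol Consistency tolerance on recomputed proportions; default
#'   `5e-5`, half of one unit in the fourth decimal.
#' @return A tibble with columns `locus`, `n_dd`, `n_di`, `n_ii`, `n`.
#' @examples
#' reconstruct_counts(load_dipplex_panel())
#' @export
reconstruct_counts <- function(summaries, tol = 5e-5) {
  abort_if(!is.data.frame(summaries), "summaries must be a data frame")
  if (!"freq_ins" %in% names(summaries)) {
    abort_if(!"freq_del" %in% names(summaries),
             "summaries need a 'freq_ins' or 'freq_del' column")
    summaries$freq_ins <- 1 - summaries$freq_del
  }
  need <- c("locus", "freq_ins", "het_obs", "n")
  missing_cols <- setdiff(need, names(summaries))
  abort_if(length(missing_cols) > 0,
           paste0("summaries lack column(s): ", paste(missing_cols, collapse = ", ")))
  if ("freq_del" %in% names(summaries)) {
    off <- abs(summaries$freq_del + summaries$freq_ins - 1)
    abort_if(any(off > tol),
             sprintf("allele frequencies at %s do not sum to 1 within %g",
                     summaries$locus[which.max(off)], tol))
  }
  purrr::pmap_dfr(summaries[need], reconstruct_one, tol = tol)
}

reconstruct_one <- function(locus, freq_ins, het_obs, n, tol) {
  abort_if(n < 1, sprintf("%s: n must be >= 1", locus))
  abort_if(het_obs < 0 || het_obs > 1, sprintf("%s: het_obs outside [0, 1]", locus))
  n_di <- round(het_obs * n)
  ins <- round(freq_ins * 2 * n)
  n_ii <- (ins - n_di) / 2
  ok <- n_ii == floor(n_ii) && n_ii >= 0 && (n - n_di - n_ii) >= 0
  if (ok) {
    n_ii <- as.integer(n_ii)
    n_dd <- as.integer(n - n_di - n_ii)
    resid <- max(abs((2 * n_ii + n_di) / (2 * n) - freq_ins), abs(n_di / n - het_obs))
    if (resid <= tol) {
      return(tibble::tibble(locus = locus, n_dd = n_dd, n_di = as.integer(n_di),
                            n_ii = n_ii, n = as.integer(n)))
    }
  }
  best <- reconstruct_search(freq_ins, het_obs, n)
  rlang::abort(sprintf(
    "%s: no integer genotype counts reproduce freq_ins=%.4f and het_obs=%.4f at n=%d within %g (closest: n_dd=%d, n_di=%d, n_ii=%d, residual %.2e)",
    locus, freq_ins, het_obs, n, tol, best$counts[1], best$counts[2], best$counts[3], best$resid))
}

# nearby-integer search used only to phrase reconstruction errors
reconstruct_search <- function(freq_ins, het_obs, n) {
  best <- list(counts = c(NA, NA, NA), resid = Inf)
  di0 <- round(het_obs * n)
  for (n_di in max(0, di0 - 2):min(n, di0 + 2)) {
    ii0 <- round((freq_ins * 2 * n - n_di) / 2)
    for (n_ii in max(0, ii0 - 2):min(n - n_di, ii0 + 2)) {
      resid <- max(abs((2 * n_ii + n_di) / (2 * n) - freq_ins), abs(n_di / n - het_obs))
      if (resid < best$resid) best <- list(counts = c(n - n_di - n_ii, n_di, n_ii), resid = resid)
    }
  }
  best
}

#' Expand per-locus genotype counts to an individual-level table
#'
#' Builds a genotype table whose per-locus genotype counts equal the input
#' exactly. Genotypes are assigned to samples by an independent seeded random
#' permutation at each locus, so single-locus statistics are reproduced
#' exactly while multi-locus phase is arbitrary (it is not recoverable from
#' per-locus summaries).
#'
#' @param counts Tibble from [reconstruct_counts()] (columns `locus`, `n_dd`,
#'   `n_di`, `n_ii`, `n`); all loci must share the same `n`.
#' @param seed Integer master seed; per-locus permutation streams are derived
#'   from it.
#' @param populations Optional character vector of length `n` of population
#'   labels to attach.
#' @param sep Allele separator used in the emitted calls.
#' @return A genotype tibble (`sample_id`, optional `population`, one column
#'   per locus).
#' @export
counts_to_genotypes <- function(counts, seed = 1L, populations = NULL, sep = "/") {
  need <- c("locus", "n_dd", "n_di", "n_ii", "n")
  missing_cols <- setdiff(need, names(counts))
  abort_if(length(missing_cols) > 0,
           paste0("counts lack column(s): ", paste(missing_cols, collapse = ", ")))
  abort_if(length(unique(counts$n)) != 1,
           "all loci must share the same sample size n")
  abort_if(any(counts$n_dd + counts$n_di + counts$n_ii != counts$n),
           "genotype counts must sum to n at every locus")
  n <- counts$n[1]
  abort_if(!is.null(populations) && length(populations) != n,
           "populations must have length n")
  geno <- c(paste0("D", sep, "D"), paste0("D", sep, "I"), paste0("I", sep, "I"))
  tbl <- tibble::tibble(sample_id = sprintf("S%04d", seq_len(n)))
  if (!is.null(populations)) tbl$population <- as.character(populations)
  cols <- purrr::pmap(counts[need], function(locus, n_dd, n_di, n_ii, n) {
    pool <- rep(geno, times = c(n_dd, n_di, n_ii))
    withr::with_seed(derive_seed(seed, match(locus, counts$locus)), sample(pool))
  })
  names(cols) <- counts$locus
  dplyr::bind_cols(tbl, tibble::as_tibble(cols))
}
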