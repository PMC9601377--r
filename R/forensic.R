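#' Polymorphism information content (Botstein)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2` for a locus with allele
#' frequency vector `freqs`. For a biallelic locus the maximum is 0.375 at
#' p = q = 0.5.
#'
#' @param freqs Numeric vector of allele frequencies (non-negative, summing
#'   to 1 within `1e-6`).
#' @return PIC as a single proportion.
#' @examples
#' pic(c(0.4422, 0.5578))
#' @export
pic <- function(freqs) {
  check_freq_vector(freqs)
  cross <- sum(outer(freqs^2, freqs^2))  # includes diagonal and both orders
  1 - sum(freqs^2) - (cross - sum(freqs^4))
}

#' Match probability and power of discrimination from genotype counts
#'
#' Match probability is the sum of squared *observed* genotype-class
#' proportions (the chance two random profiles coincide at the locus);
#' power of discrimination is its complement, `PD = 1 - PM`.
#'
#' @param counts Numeric vector of genotype-class counts (any number of
#'   classes; for a biallelic locus `c(n_dd, n_di, n_ii)`).
#' @return A single proportion.
#' @examples
#' match_probability(c(153, 288, 190))
#' power_of_discrimination(c(153, 288, 190))
#' @export
match_probability <- function(counts) {
  abort_if(any(counts < 0) || sum(counts) < 1, "counts must be non-negative with n >= 1")
  sum((counts / sum(counts))^2)
}

#' @rdname match_probability
#' @export
power_of_discrimination <- function(counts) 1 - match_probability(counts)

#' Power of exclusion
#'
#' Brenner/Fisher formulation `PE = h^2 (1 - 2 h H^2)` with `h` the observed
#' heterozygote proportion and `H = 1 - h`.
#'
#' @param het_obs Observed heterozygosity in `[0, 1]`.
#' @return A single proportion; increasing in `het_obs`.
#' @export
power_of_exclusion <- function(het_obs) {
  abort_if(any(het_obs < 0 | het_obs > 1), "het_obs must lie in [0, 1]")
  H <- 1 - het_obs
  het_obs^2 * (1 - 2 * het_obs * H^2)
}

#' Typical paternity index
#'
#' `TPI = 1 / (2 H)` with `H = 1 - het_obs` the homozygote proportion.
#'
#' @inheritParams power_of_exclusion
#' @return A positive ratio; errors when `het_obs = 1` (infinite index).
#' @export
typical_paternity_index <- function(het_obs) {
  abort_if(any(het_obs < 0 | het_obs > 1), "het_obs must lie in [0, 1]")
  abort_if(any(het_obs == 1), "TPI is infinite at het_obs = 1")
  1 / (2 * (1 - het_obs))
}

#' Nei's unbiased expected heterozygosity
#'
#' Gene diversity with the small-sample correction,
#' `(2n / (2n - 1)) * (1 - sum(p^2))`.
#'
#' @inheritParams pic
#' @param n Number of diploid individuals (`n >= 1`).
#' @return A single proportion.
#' @export
unbiased_expected_heterozygosity <- function(freqs, n) {
  check_freq_vector(freqs)
  abort_if(n < 1, "n must be >= 1")
  (2 * n / (2 * n - 1)) * (1 - sum(freqs^2))
}

# vectorised biallelic version used internally
unbiased_expected_heterozygosity_vec <- function(p, q, n) {
  (2 * n / (2 * n - 1)) * (1 - p^2 - q^2)
}

#' Per-locus summaries and combined indexes from genotype counts
#'
#' Computes one summary row per biallelic locus from its genotype counts:
#' allele frequencies, observed and unbiased expected heterozygosity, PIC,
#' match probability, PD, PE, TPI and a Hardy-Weinberg p-value (Levene exact
#' enumeration by default, or the Monte-Carlo allele re-pairing test), plus
#' the panel-level combined indexes cPM, cPD, cPE.
#'
#' @param counts Tibble with columns `locus`, `n_dd`, `n_di`, `n_ii`, `n`
#'   (from [count_genotypes()] or [reconstruct_counts()]).
#' @param hwe_method `"exact"` (default) or `"permutation"`.
#' @param n_perm Permutations for the Monte-Carlo HWE test (default 10000).
#' @param seed Master seed for the permutation test; per-locus streams are
#'   derived from it.
#' @return An object of class `indel_panel`; [tidy()][generics::tidy] returns
#'   the per-locus tibble, [glance()][generics::glance] the one-row combined
#'   index tibble, and `autoplot()` a per-locus parameter chart.
#' @examples
#' panel <- summarize_counts(reconstruct_counts(load_dipplex_panel()))
#' glance(panel)
#' @export
summarize_counts <- function(counts, hwe_method = c("exact", "permutation"),
                             n_perm = 10000L, seed = 1L) {
  hwe_method <- match.arg(hwe_method)
  need <- c("locus", "n_dd", "n_di", "n_ii", "n")
  missing_cols <- setdiff(need, names(counts))
  abort_if(length(missing_cols) > 0,
           paste0("counts lack column(s): ", paste(missing_cols, collapse = ", ")))
  abort_if(any(counts$n < 1), sprintf("locus %s has n = 0 (all calls missing)",
                                      counts$locus[which(counts$n < 1)[1]]))
  loci <- purrr::pmap_dfr(
    counts[need],
    function(locus, n_dd, n_di, n_ii, n) {
      p_ins <- (2 * n_ii + n_di) / (2 * n)
      h <- n_di / n
      p_hwe <- switch(hwe_method,
        exact = hwe_exact_p(n_dd, n_di, n_ii),
        permutation = hwe_permutation_p(n_dd, n_di, n_ii, n_perm = n_perm,
                                        seed = derive_seed(seed, match(locus, counts$locus))))
      pm <- match_probability(c(n_dd, n_di, n_ii))
      tibble::tibble(
        locus = locus, n = n,
        freq_del = 1 - p_ins, freq_ins = p_ins,
        het_obs = h,
        het_exp = unbiased_expected_heterozygosity_vec(p_ins, 1 - p_ins, n),
        pic = pic(c(1 - p_ins, p_ins)),
        pm = pm, pd = 1 - pm,
        pe = power_of_exclusion(h),
        tpi = if (h < 1) typical_paternity_index(h) else NA_real_,
        p_hwe = p_hwe)
    })
  structure(
    list(loci = loci, combined = combined_indexes(loci),
         hwe_method = hwe_method, n_perm = if (hwe_method == "permutation") n_perm else NA_integer_,
         seed = seed),
    class = "indel_panel")
}

#' Summarise a genotype table into a forensic panel report
#'
#' Convenience wrapper collapsing an individual-level D/I genotype table to
#' per-locus counts (missing calls excluded per locus) and delegating to
#' [summarize_counts()].
#'
#' @param tbl Genotype tibble.
#' @inheritParams summarize_counts
#' @inheritParams write_genotypes
#' @return An `indel_panel` object.
#' @export
summarize_panel <- function(tbl, hwe_method = c("exact", "permutation"),
                            n_perm = 10000L, seed = 1L, sep = "/", missing = "./.") {
  counts <- count_genotypes(tbl, sep = sep, missing = missing)
  summarize_counts(counts, hwe_method = hwe_method, n_perm = n_perm, seed = seed)
}

#' Combined forensic identification indexes
#'
#' `cPM` is the product of per-locus match probabilities, `cPD = 1 - cPM`,
#' and `cPE = 1 - prod(1 - PE_l)`.
#'
#' @param loci Per-locus tibble with columns `pm` and `pe` (as produced by
#'   [summarize_counts()]).
#' @return One-row tibble with `cpm`, `cpd`, `cpe`.
#' @export
combined_indexes <- function(loci) {
  abort_if(nrow(loci) < 1, "need at least one locus")
  cpm <- prod(loci$pm)
  tibble::tibble(cpm = cpm, cpd = 1 - cpm, cpe = 1 - prod(1 - loci$pe))
}

#' Write a panel summary as a published-style delimited report
#'
#' Emits the per-locus table in the conventional column order with values
#' rounded to 4 decimals (frequencies are stored at full precision; rounding
#' happens only here, at report time).
#'
#' @param x An `indel_panel` object.
#' @param path Output path (`.csv` or tab-delimited).
#' @return `path`, invisibly.
#' @export
write_panel_report <- function(x, path) {
  stopifnot(inherits(x, "indel_panel"))
  rep4 <- dplyr::mutate(x$loci, dplyr::across(dplyr::where(is.double), ~ round(.x, 4)))
  rep4 <- dplyr::select(rep4, "locus", "freq_del", "freq_ins", "het_obs",
                        "het_exp", "p_hwe", "pic", "pd", "pe", "tpi")
  if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::write_csv(rep4, path)
  else readr::write_tsv(rep4, path)
  invisible(path)
}

#' @export
print.indel_panel <- function(x, ...) {
  cat(sprintf("Forensic InDel panel summary: %d loci (HWE: %s)\n",
              nrow(x$loci), x$hwe_method))
  cat(sprintf("  cPM = %.4e   cPD = %.15f   cPE = %.4f\n",
              x$combined$cpm, x$combined$cpd, x$combined$cpe))
  print(x$loci, n = 10)
  invisible(x)
}

#' @importFrom generics tidy
#' @exportS3Method generics::tidy
tidy.indel_panel <- function(x, ...) x$loci

#' @importFrom generics glance
#' @exportS3Method generics::glance
glance.indel_panel <- function(x, ...) x$combined

#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.indel_panel <- function(object, ...) {
  long <- tidyr::pivot_longer(object$loci,
                              cols = c("pic", "pd", "pe", "het_obs", "het_exp"),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$locus, .data$value),
                                     y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-locus forensic efficiency parameters") +
    ggplot2::theme_minimal(base_size = 9)
}

check_freq_vector <- function(freqs, tol = 1e-6) {
  abort_if(length(freqs) < 1 || any(!is.finite(freqs)) || any(freqs < 0),
           "allele frequencies must be finite and non-negative")
  abort_if(abs(sum(freqs) - 1) > tol, "allele frequencies must sum to 1")
}
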