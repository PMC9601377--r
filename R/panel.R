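#' The published 30-locus DIPplex reference panel (Polish sample, n = 631)
#'
#' Loads the bundled per-locus summary table for the 30 Investigator DIPplex
#' InDel loci typed in a sample of 631 unrelated Polish individuals: allele
#' frequencies of the deletion (DIP-) and insertion (DIP+) alleles, the two
#' printed heterozygosity columns, the Hardy-Weinberg p-value and the
#' forensic efficiency parameters (PIC, PD, PE, TPI).
#'
#' The published table labels its heterozygosity columns "Ho" (observed) and
#' "He" (expected), but the numbers are the other way around: the "Ho" column
#' equals Nei's unbiased expected heterozygosity `2pq * 2n/(2n-1)` at every
#' locus to 4 decimals, while the "He" column contains values (0.5436 at
#' HLD93) that exceed the biallelic expected-heterozygosity maximum of about
#' 0.5004 attainable at n = 631. The loader therefore maps the "Ho" column to
#' `het_exp` and the "He" column to `het_obs`, and with `verify = TRUE`
#' (default) re-derives both facts numerically from the frequencies before
#' returning, erroring if either check fails.
#'
#' @param verify Logical; re-check the heterozygosity column assignment
#'   numerically (default `TRUE`).
#' @return A tibble with one row per locus: `locus`, `location` (cytogenetic
#'   band), `rs_id`, `freq_del`, `freq_ins`, `het_obs`, `het_exp`, `p_hwe`,
#'   `pic`, `pd`, `pe`, `tpi`, `n`.
#' @examples
#' panel <- load_dipplex_panel()
#' dplyr::filter(panel, locus == "HLD77")
#' @export
load_dipplex_panel <- function(verify = TRUE) {
  path <- system.file("extdata", "dipplex_polish_panel.csv", package = "indelpop",
                      mustWork = TRUE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  n <- 631L
  panel <- tibble::tibble(
    locus = raw$locus, location = raw$location, rs_id = raw$rs_id,
    freq_del = raw$freq_del, freq_ins = raw$freq_ins,
    het_obs = raw$he, het_exp = raw$ho,
    p_hwe = raw$p_hwe, pic = raw$pic, pd = raw$pd, pe = raw$pe, tpi = raw$tpi,
    n = n
  )
  if (verify) {
    uhe <- unbiased_expected_heterozygosity_vec(panel$freq_del, panel$freq_ins, n)
    dev <- max(abs(round(uhe, 4) - panel$het_exp))
    # printed frequencies are rounded to 4 dp, so allow one unit in the 4th place
    abort_if(dev > 1.5e-4,
             "heterozygosity column check failed: 'Ho' column does not match unbiased expected heterozygosity")
    he_max <- (2 * n / (2 * n - 1)) * 0.5
    abort_if(!any(panel$het_obs > he_max + 1e-4),
             "heterozygosity column check failed: 'He' column never exceeds the expected-heterozygosity bound")
    rlang::inform(
      paste("dipplex panel: printed 'Ho' column verified as unbiased expected",
            "heterozygosity and 'He' as observed heterozygosity; columns mapped accordingly"),
      .frequency = "once", .frequency_id = "indelpop_dipplex_columns")
  }
  panel
}

#' Published worldwide pairwise FST matrix (20 populations)
#'
#' The published matrix of sample-bias-corrected pairwise FST distances
#' between the Polish sample and 19 reference populations, as a symmetric
#' distance matrix ready for [nj_tree()] and [mds_smacof()]. Population codes
#' follow the source (POL, ESP, MEX, KOR, FIN, SOM, PAK, ZAZ, IRQ, LTU, SLO,
#' TUR, VIE, NGA, BHR, ZAA, ANG, MOZ, BRA, CHN).
#'
#' @return A 20 x 20 symmetric numeric matrix with population codes as labels.
#' @export
load_worldwide_fst <- function() {
  read_dist_phylip(system.file("extdata", "worldwide_fst_phylip.txt",
                               package = "indelpop", mustWork = TRUE))
}
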