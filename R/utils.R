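# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic stream-seed derivation: one master seed fans out to
# per-locus / per-population / per-permutation streams so results do not
# depend on evaluation order. Kept inside 32-bit signed integer range.
derive_seed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, length(stream) >= 1L)
  as.integer((as.numeric(seed) %% 2147483629 * 48271 +
                as.numeric(stream) * 8191 + 1) %% 2147483629)
}

meta_cols <- c("sample_id", "population")

locus_columns <- function(tbl) setdiff(names(tbl), meta_cols)

abort_if <- function(cond, msg) if (cond) rlang::abort(msg)

# pair ordering used to normalise unordered genotype calls: numeric labels
# sort numerically (STR alleles "8" < "10"), anything else byte-wise
allele_pair_sorted <- function(a1, a2) {
  n1 <- suppressWarnings(as.numeric(a1))
  n2 <- suppressWarnings(as.numeric(a2))
  numeric_pair <- !is.na(n1) & !is.na(n2)
  swap <- ifelse(numeric_pair, n1 > n2, as.character(a1) > as.character(a2))
  swap[is.na(swap)] <- FALSE
  list(first = ifelse(swap, a2, a1), second = ifelse(swap, a1, a2))
}
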