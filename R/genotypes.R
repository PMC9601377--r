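#' Read a diploid genotype table
#'
#' Reads a delimited text file of diploid genotype calls into a tibble with
#' one row per sample and one column per locus. The first column must be
#' `sample_id`; an optional `population` column carries a group label. Every
#' remaining column is a locus whose cells are calls of the form `"A1/A2"`
#' (unordered allele pair) or the missing-data token. Calls are normalised on
#' read so that `"I/D"` and `"D/I"` become the same genotype.
#'
#' @param path Path to a CSV (`.csv`) or tab-delimited file (anything else).
#' @param sep Allele separator inside a call, default `"/"`.
#' @param missing Missing-genotype token, default `"./."`.
#' @param alleles Optional character vector (or named list, one entry per
#'   locus) of permitted allele labels; calls using any other label raise a
#'   validation error. `NULL` (default) accepts any label.
#' @return A tibble with columns `sample_id`, optionally `population`, and
#'   one character column per locus.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,HLD77,HLD45", "S1,D/I,I/I", "S2,D/D,I/D"), tf)
#' read_genotypes(tf)
#' @export
read_genotypes <- function(path, sep = "/", missing = "./.", alleles = NULL) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  tbl <- read_delim_auto(path)
  abort_if(!"sample_id" %in% names(tbl), "genotype file must have a 'sample_id' column")
  tbl <- dplyr::mutate(tbl, dplyr::across(dplyr::everything(), as.character))
  for (loc in locus_columns(tbl)) {
    tbl[[loc]] <- normalize_calls(tbl[[loc]], loc, sep = sep, missing = missing,
                                  alleles = allele_set_for(alleles, loc))
  }
  validate_genotypes(tbl, sep = sep, missing = missing)
  tbl
}

#' Write a diploid genotype table
#'
#' Emits delimited text re-readable by [read_genotypes()]; a write/read round
#' trip reproduces the table exactly.
#'
#' @param tbl Genotype tibble as produced by [read_genotypes()] or the
#'   simulators.
#' @param path Output path; `.csv` writes comma-separated, anything else tabs.
#' @inheritParams read_genotypes
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(tbl, path, sep = "/", missing = "./.") {
  validate_genotypes(tbl, sep = sep, missing = missing)
  out <- tbl
  for (loc in locus_columns(out)) out[[loc]][is.na(out[[loc]])] <- missing
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(out, path)
  } else {
    readr::write_tsv(out, path)
  }
  invisible(path)
}

#' Validate a genotype table
#'
#' Checks the structural invariants of a genotype tibble: unique non-missing
#' sample identifiers, at least one locus column, and every cell either the
#' missing token (stored as `NA`) or a two-allele call.
#'
#' @inheritParams write_genotypes
#' @return The table, invisibly; errors describe the first violation found.
#' @export
validate_genotypes <- function(tbl, sep = "/", missing = "./.") {
  abort_if(!is.data.frame(tbl), "genotype table must be a data frame")
  abort_if(!"sample_id" %in% names(tbl), "missing 'sample_id' column")
  ids <- tbl$sample_id
  abort_if(anyNA(ids) || any(ids == ""), "sample_id contains empty values")
  dup <- ids[duplicated(ids)]
  abort_if(length(dup) > 0, paste0("duplicate sample_id: ", dup[1]))
  loci <- locus_columns(tbl)
  abort_if(length(loci) == 0, "genotype table has no locus columns")
  for (loc in loci) {
    cells <- tbl[[loc]]
    bad <- !is.na(cells) & !grepl(paste0("^[^", sep, "]+", sep, "[^", sep, "]+$"),
                                  cells, fixed = FALSE)
    if (any(bad)) {
      row <- which(bad)[1]
      rlang::abort(sprintf("malformed genotype cell at row %d, locus %s: '%s'",
                           row, loc, cells[row]))
    }
  }
  invisible(tbl)
}

#' Per-locus biallelic genotype counts
#'
#' Collapses a D/I genotype table to its sufficient statistic: the counts of
#' the three genotype classes at each locus. Missing calls are dropped per
#' locus (complete-case `n`).
#'
#' @inheritParams write_genotypes
#' @return A tibble with columns `locus`, `n_dd`, `n_di`, `n_ii`, `n`.
#' @export
count_genotypes <- function(tbl, sep = "/", missing = "./.") {
  validate_genotypes(tbl, sep = sep, missing = missing)
  di <- c(paste0("D", sep, "D"), paste0("D", sep, "I"), paste0("I", sep, "I"))
  purrr::map_dfr(locus_columns(tbl), function(loc) {
    calls <- tbl[[loc]][!is.na(tbl[[loc]])]
    unknown <- setdiff(unique(calls), di)
    abort_if(length(unknown) > 0,
             sprintf("locus %s has non-D/I call '%s'; count_genotypes expects biallelic D/I loci",
                     loc, unknown[1]))
    tibble::tibble(locus = loc,
                   n_dd = sum(calls == di[1]),
                   n_di = sum(calls == di[2]),
                   n_ii = sum(calls == di[3]),
                   n = length(calls))
  })
}

#' Allele frequencies from a genotype table
#'
#' @inheritParams write_genotypes
#' @return A long tibble with columns `locus`, `allele`, `count`, `freq`,
#'   `n` (individuals with a non-missing call at that locus).
#' @export
allele_frequencies <- function(tbl, sep = "/", missing = "./.") {
  validate_genotypes(tbl, sep = sep, missing = missing)
  purrr::map_dfr(locus_columns(tbl), function(loc) {
    calls <- tbl[[loc]][!is.na(tbl[[loc]])]
    abort_if(length(calls) == 0, sprintf("locus %s has no non-missing calls", loc))
    al <- unlist(strsplit(calls, sep, fixed = TRUE), use.names = FALSE)
    cnt <- table(al)
    tibble::tibble(locus = loc, allele = names(cnt),
                   count = as.integer(cnt),
                   freq = as.numeric(cnt) / length(al),
                   n = length(calls))
  })
}

#' Per-population allele frequencies
#'
#' Splits a genotype table by its `population` column and computes allele
#' frequencies within each population, yielding the long-format frequency
#' table consumed by the FST, tree and ordination machinery.
#'
#' @inheritParams write_genotypes
#' @return A tibble with columns `population`, `locus`, `allele`, `freq`, `n`.
#' @export
population_frequencies <- function(tbl, sep = "/", missing = "./.") {
  abort_if(!"population" %in% names(tbl) || anyNA(tbl$population),
           "population_frequencies needs a complete 'population' column")
  purrr::map_dfr(split(tbl, tbl$population), function(sub) {
    dplyr::mutate(allele_frequencies(sub, sep = sep, missing = missing),
                  population = sub$population[1], .before = 1) |>
      dplyr::select(-"count")
  })
}

# ---- frequency-table io ----------------------------------------------------

#' Read a population allele-frequency table
#'
#' Long-format delimited file with columns `population`, `locus`, `allele`,
#' `freq`, `n`. Within each population x locus the frequencies must be
#' non-negative and sum to 1; deviations up to `1e-6` are renormalised,
#' larger ones are an error.
#'
#' @param path CSV or tab-delimited file.
#' @return A validated tibble in the same long format.
#' @export
read_frequency_table <- function(path) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  tbl <- read_delim_auto(path)
  need <- c("population", "locus", "allele", "freq", "n")
  missing_cols <- setdiff(need, names(tbl))
  abort_if(length(missing_cols) > 0,
           paste0("frequency table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  tbl <- dplyr::mutate(tbl, freq = as.numeric(.data$freq), n = as.numeric(.data$n))
  validate_frequency_table(tbl)
}

#' Write a population allele-frequency table
#'
#' @param tbl Long-format frequency tibble (see [read_frequency_table()]).
#' @param path Output path; `.csv` writes comma-separated, anything else tabs.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(tbl, path) {
  validate_frequency_table(tbl)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(tbl, path)
  } else {
    readr::write_tsv(tbl, path)
  }
  invisible(path)
}

validate_frequency_table <- function(tbl, tol = 1e-6) {
  abort_if(any(tbl$freq < 0), "negative allele frequency")
  abort_if(any(tbl$n < 1), "population sample sizes must be >= 1")
  dplyr::group_by(tbl, .data$population, .data$locus) |>
    dplyr::group_modify(function(g, key) {
      s <- sum(g$freq)
      abort_if(abs(s - 1) > tol,
               sprintf("allele frequencies for %s / %s sum to %.8f (off by > %g)",
                       key$population, key$locus, s, tol))
      g$freq <- g$freq / s
      g
    }) |>
    dplyr::ungroup()
}

# ---- internals -------------------------------------------------------------

read_delim_auto <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

allele_set_for <- function(alleles, locus) {
  if (is.null(alleles)) return(NULL)
  if (is.list(alleles)) alleles[[locus]] else alleles
}

normalize_calls <- function(cells, locus, sep, missing, alleles = NULL) {
  out <- as.character(cells)
  out[out == missing | is.na(out)] <- NA_character_
  present <- which(!is.na(out))
  if (length(present) == 0) return(out)
  parts <- strsplit(out[present], sep, fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != 2)) {
    row <- present[which(lens != 2)[1]]
    rlang::abort(sprintf("malformed genotype cell at row %d, locus %s: '%s'",
                         row, locus, cells[row]))
  }
  a1 <- vapply(parts, `[[`, "", 1L)
  a2 <- vapply(parts, `[[`, "", 2L)
  if (!is.null(alleles)) {
    bad <- !(a1 %in% alleles) | !(a2 %in% alleles)
    if (any(bad)) {
      row <- present[which(bad)[1]]
      rlang::abort(sprintf("unknown allele label at row %d, locus %s: '%s'",
                           row, locus, cells[row]))
    }
  }
  srt <- allele_pair_sorted(a1, a2)
  out[present] <- paste0(srt$first, sep, srt$second)
  out
}
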