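#' Write a distance matrix in PHYLIP square format
#'
#' First line holds the taxon count; each following line holds a label and
#' its full row of distances. Labels longer than 10 characters are written in
#' relaxed PHYLIP (full label followed by whitespace), which every modern
#' reader accepts.
#'
#' @param m Symmetric numeric matrix with `dimnames`, zero diagonal.
#' @param path Output file.
#' @param digits Decimal places written (default 6).
#' @return `path`, invisibly.
#' @export
write_dist_phylip <- function(m, path, digits = 6) {
  validate_distance_matrix(m)
  labs <- rownames(m)
  fmt <- paste0("%.", digits, "f")
  lines <- c(as.character(nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(labs[i], sprintf(fmt, m[i, ])), collapse = "  ")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path File written by [write_dist_phylip()] or any square-format
#'   PHYLIP distance file (strict or relaxed labels).
#' @return Symmetric numeric matrix with labels as `dimnames`.
#' @export
read_dist_phylip <- function(path) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  k <- suppressWarnings(as.integer(trimws(lines[1])))
  abort_if(is.na(k) || k < 1, "first line must hold the taxon count")
  abort_if(length(lines) < k + 1, "fewer matrix rows than declared taxa")
  labs <- character(k)
  m <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    toks <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    abort_if(length(toks) != k + 1,
             sprintf("row %d has %d fields, expected %d", i, length(toks), k + 1))
    labs[i] <- toks[1]
    m[i, ] <- as.numeric(toks[-1])
  }
  dimnames(m) <- list(labs, labs)
  validate_distance_matrix(m)
  m
}

validate_distance_matrix <- function(m, tol = 1e-12) {
  abort_if(!is.matrix(m) || !is.numeric(m), "distance matrix must be numeric")
  abort_if(nrow(m) != ncol(m), "distance matrix must be square")
  abort_if(is.null(rownames(m)), "distance matrix needs row/column labels")
  abort_if(any(!is.finite(m)), "non-finite distances")
  abort_if(any(abs(diag(m)) > tol), "diagonal must be zero")
  abort_if(max(abs(m - t(m))) > tol, "distance matrix must be symmetric")
  abort_if(any(m < -tol), "distances must be non-negative")
  invisible(m)
}
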