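#' SMACOF multidimensional scaling of a distance matrix
#'
#' Metric MDS by stress majorization: starting from the classical-scaling
#' (Torgerson) configuration, the configuration is updated by the Guttman
#' transform until the drop in raw stress falls below `tol` or `max_iter`
#' is reached. The majorization guarantee makes stress non-increasing at
#' every step, and the deterministic initialisation makes the result
#' reproducible without a seed. Reported stress is normalised stress-1,
#' `sqrt(sum((d - dhat)^2) / sum(d^2))`.
#'
#' @param m Symmetric distance matrix with labels.
#' @param ndim Embedding dimension (default 2).
#' @param tol Convergence threshold on the raw-stress decrease (default
#'   `1e-8`).
#' @param max_iter Iteration cap (default 10000).
#' @return An object of class `indel_mds` with elements `points` (centered
#'   coordinate matrix), `stress` (normalised stress-1), `stress_trace`,
#'   `n_iter`. `tidy()` returns a tibble of coordinates; `autoplot()` draws
#'   the labelled ordination.
#' @examples
#' mds_smacof(load_worldwide_fst())
#' @export
mds_smacof <- function(m, ndim = 2, tol = 1e-8, max_iter = 10000L) {
  validate_distance_matrix(m, tol = 1e-8)
  abort_if(ndim < 1, "ndim must be >= 1")
  n <- nrow(m)
  labs <- rownames(m)
  delta <- unname(m)
  if (all(delta == 0)) {
    pts <- matrix(0, n, ndim, dimnames = list(labs, paste0("dim", seq_len(ndim))))
    return(structure(list(points = pts, stress = 0, stress_trace = 0, n_iter = 0L),
                     class = "indel_mds"))
  }
  x <- stats::cmdscale(stats::as.dist(delta), k = min(ndim, n - 1))
  if (ncol(x) < ndim) x <- cbind(x, matrix(0, n, ndim - ncol(x)))
  x <- scale(x, center = TRUE, scale = FALSE)
  raw_stress <- function(x) {
    dx <- as.matrix(stats::dist(x))
    sum((delta - dx)[upper.tri(delta)]^2)
  }
  s <- raw_stress(x)
  trace <- s
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    dx <- as.matrix(stats::dist(x))
    ratio <- ifelse(dx > 0, delta / dx, 0)
    b <- -ratio
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x_new <- b %*% x / n
    x_new <- scale(x_new, center = TRUE, scale = FALSE)
    s_new <- raw_stress(x_new)
    abort_if(s_new > s + 1e-9, "stress increased; majorization failure")
    x <- x_new
    trace <- c(trace, s_new)
    if (s - s_new < tol) { s <- s_new; break }
    s <- s_new
  }
  stress1 <- sqrt(s / sum(delta[upper.tri(delta)]^2))
  dimnames(x) <- list(labs, paste0("dim", seq_len(ndim)))
  structure(list(points = x, stress = stress1, stress_trace = trace,
                 n_iter = iter),
            class = "indel_mds")
}

#' @export
print.indel_mds <- function(x, ...) {
  cat(sprintf("SMACOF MDS: %d points in %d dimensions, stress-1 = %.6f (%d iterations)\n",
              nrow(x$points), ncol(x$points), x$stress, x$n_iter))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.indel_mds <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(label = rownames(x$points)),
                   tibble::as_tibble(x$points))
}

#' @exportS3Method generics::glance
glance.indel_mds <- function(x, ...) {
  tibble::tibble(n = nrow(x$points), ndim = ncol(x$points),
                 stress = x$stress, n_iter = x$n_iter)
}

#' @exportS3Method ggplot2::autoplot
autoplot.indel_mds <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                   label = .data$label)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_text(vjust = -0.7, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Dimension 1", y = "Dimension 2",
                  title = sprintf("SMACOF ordination (stress-1 = %.4f)", object$stress)) +
    ggplot2::theme_minimal()
}

#' Write MDS coordinates as a delimited table
#'
#' Emits `label`, coordinate columns and a `stress` header comment line.
#'
#' @param x An `indel_mds` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mds_coords <- function(x, path) {
  stopifnot(inherits(x, "indel_mds"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalised stress-1: %.8f", x$stress), con)
  utils::write.table(tidy(x), con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
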