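#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of tests (`m >= 1`).
#' @return `alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 30)   # per-locus HWE gate
#' bonferroni_alpha(0.05, 435)  # all pairs of 30 loci
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  abort_if(m < 1, "m must be >= 1")
  abort_if(alpha <= 0 || alpha >= 1, "alpha must lie in (0, 1)")
  alpha / m
}

#' EM haplotype-frequency estimation for two unphased loci
#'
#' Maximum-likelihood two-locus haplotype frequencies under random union of
#' gametes, estimated by expectation-maximisation over the phase ambiguity of
#' double heterozygotes (Excoffier-Slatkin). Works for any numbers of alleles
#' at either locus; for multiallelic pairs, seeded random restarts guard
#' against local optima.
#'
#' @param calls_a,calls_b Character vectors of genotype calls (`"A1/A2"`) at
#'   the two loci for the same samples; pairs with a missing call at either
#'   locus are dropped.
#' @param tol EM stops when the log-likelihood gain falls below this
#'   (default `1e-8`).
#' @param max_iter Iteration cap (default 1000).
#' @param n_restarts Number of EM starts; the first uses linkage-equilibrium
#'   frequencies, the rest random Dirichlet draws. `NULL` (default) picks 1
#'   for biallelic x biallelic pairs and 3 otherwise.
#' @param seed Seed for restart draws.
#' @param sep Allele separator inside calls.
#' @return A list with `haplotypes` (tibble `allele_a`, `allele_b`, `freq`),
#'   `logL`, `logL_null` (log-likelihood at allele-frequency products),
#'   `n_iter`, `converged`.
#' @examples
#' a <- rep(c("D/D", "I/I"), each = 50)
#' em_haplotypes(a, a)$haplotypes
#' @export
em_haplotypes <- function(calls_a, calls_b, tol = 1e-8, max_iter = 1000L,
                          n_restarts = NULL, seed = 1L, sep = "/") {
  abort_if(length(calls_a) != length(calls_b), "call vectors must have equal length")
  keep <- !is.na(calls_a) & !is.na(calls_b)
  abort_if(sum(keep) < 1, "no samples with complete calls at both loci")
  ea <- locus_encoding(calls_a[keep], sep)
  eb <- locus_encoding(calls_b[keep], sep)
  st <- pair_structure(ea$k, eb$k)
  cnt <- tabulate((ea$code - 1L) * st$KB + eb$code, nbins = st$n_class)
  n_restarts <- n_restarts %||% (if (ea$k <= 2 && eb$k <= 2) 1L else 3L)
  fit <- em_best_fit(cnt, st, ea, eb, tol, max_iter, n_restarts, seed)
  hap <- tidyr::expand_grid(allele_a = ea$alleles, allele_b = eb$alleles)
  hap$freq <- fit$f  # haplotype index is (i-1)*kb + j, locus-b allele fastest
  list(haplotypes = hap, logL = fit$logL, logL_null = fit$logL_null,
       n_iter = fit$n_iter, converged = fit$converged)
}

#' Likelihood-ratio permutation test of linkage disequilibrium
#'
#' Tests gametic association between two loci of a genotype table. The
#' statistic is `-2 (logL_null - logL_full)` where the full model is the EM
#' haplotype-frequency estimate and the null fixes haplotype frequencies at
#' the products of single-locus allele frequencies. Significance comes from
#' permuting one locus's genotype column across samples (which preserves
#' both single-locus genotype distributions) and recomputing the statistic,
#' with the add-one p estimator.
#'
#' @param tbl Genotype tibble.
#' @param locus_a,locus_b Names of the two locus columns.
#' @param n_perm Number of permutations (default 10000, the conventional
#'   setting for forensic panels).
#' @param seed Integer seed; the test is deterministic given it.
#' @inheritParams em_haplotypes
#' @return One-row tibble: `locus_a`, `locus_b`, `lr_stat`, `p_perm`,
#'   `n_perm`, `seed`; the EM haplotype table is attached as attribute
#'   `"haplotypes"`.
#' @export
ld_test <- function(tbl, locus_a, locus_b, n_perm = 10000L, seed = 1L,
                    tol = 1e-8, max_iter = 1000L, n_restarts = NULL, sep = "/") {
  abort_if(n_perm < 1, "n_perm must be >= 1")
  abort_if(!all(c(locus_a, locus_b) %in% names(tbl)),
           "locus_a and locus_b must be columns of the genotype table")
  ca <- tbl[[locus_a]]; cb <- tbl[[locus_b]]
  keep <- !is.na(ca) & !is.na(cb)
  ca <- ca[keep]; cb <- cb[keep]
  ea <- locus_encoding(ca, sep)
  eb <- locus_encoding(cb, sep)
  st <- pair_structure(ea$k, eb$k)
  n_restarts <- n_restarts %||% (if (ea$k <= 2 && eb$k <= 2) 1L else 3L)
  stat <- function(code_b, restart_seed) {
    cnt <- tabulate((ea$code - 1L) * st$KB + code_b, nbins = st$n_class)
    fit <- em_best_fit(cnt, st, ea, eb, tol, max_iter, n_restarts, restart_seed)
    max(-2 * (fit$logL_null - fit$logL), 0)
  }
  lr_obs <- stat(eb$code, derive_seed(seed, 0L))
  obs_fit <- em_haplotypes(ca, cb, tol = tol, max_iter = max_iter,
                           n_restarts = n_restarts, seed = derive_seed(seed, 0L), sep = sep)
  lr_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat(sample(eb$code), derive_seed(seed, i)),
           numeric(1))
  })
  p <- (1 + sum(lr_perm >= lr_obs - 1e-9)) / (n_perm + 1)
  out <- tibble::tibble(locus_a = locus_a, locus_b = locus_b,
                        lr_stat = lr_obs, p_perm = p,
                        n_perm = as.integer(n_perm), seed = as.integer(seed))
  attr(out, "haplotypes") <- obs_fit$haplotypes
  out
}

#' Linkage-disequilibrium tests over all locus pairs
#'
#' Runs [ld_test()] on every unordered pair of loci (30 loci give 435
#' pairs), with per-pair seeds derived reproducibly from one master seed, and
#' flags pairs significant after Bonferroni correction for the number of
#' pairs.
#'
#' @inheritParams ld_test
#' @param alpha Family-wise level for the Bonferroni flag (default 0.05).
#' @inheritParams write_genotypes
#' @return Tibble with one row per pair: `locus_a`, `locus_b`, `lr_stat`,
#'   `p_perm`, `n_perm`, `seed`, `significant`.
#' @export
ld_all_pairs <- function(tbl, n_perm = 10000L, seed = 1L, alpha = 0.05,
                         sep = "/", missing = "./.") {
  loci <- locus_columns(tbl)
  abort_if(length(loci) < 2, "need at least two loci")
  pairs <- utils::combn(loci, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    ld_test(tbl, pairs[1, k], pairs[2, k], n_perm = n_perm,
            seed = derive_seed(seed, k), sep = sep)
  })
  res$significant <- res$p_perm < bonferroni_alpha(alpha, ncol(pairs))
  res
}

# ---- internals -------------------------------------------------------------

sort_alleles <- function(labels) {
  nums <- suppressWarnings(as.numeric(labels))
  if (!anyNA(nums)) labels[order(nums)] else sort(labels, method = "radix")
}

locus_encoding <- function(calls, sep = "/") {
  parts <- strsplit(calls, sep, fixed = TRUE)
  abort_if(any(lengths(parts) != 2), "malformed genotype call")
  a1 <- vapply(parts, `[[`, "", 1L)
  a2 <- vapply(parts, `[[`, "", 2L)
  alleles <- sort_alleles(unique(c(a1, a2)))
  i1 <- match(a1, alleles); i2 <- match(a2, alleles)
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  list(alleles = alleles, k = length(alleles),
       code = as.integer(hi * (hi - 1L) / 2L + lo))
}

# unordered allele pairs in code order (hi ascending, lo = 1..hi)
pair_table <- function(k) {
  do.call(rbind, lapply(seq_len(k), function(hi) cbind(seq_len(hi), hi)))
}

# Enumerates, for every joint genotype class of a locus pair, its phase
# resolutions: the (unordered) haplotype pairs consistent with the class,
# with multiplicity 2 when the two haplotypes differ.
pair_structure <- function(ka, kb) {
  pa <- pair_table(ka); pb <- pair_table(kb)
  KA <- nrow(pa); KB <- nrow(pb)
  hap <- function(i, j) (i - 1L) * kb + j
  U <- V <- M <- CLS <- integer(0)
  for (ga in seq_len(KA)) {
    for (gb in seq_len(KB)) {
      jc <- (ga - 1L) * KB + gb
      r1 <- sort(unname(c(hap(pa[ga, 1], pb[gb, 1]), hap(pa[ga, 2], pb[gb, 2]))))
      r2 <- sort(unname(c(hap(pa[ga, 1], pb[gb, 2]), hap(pa[ga, 2], pb[gb, 1]))))
      for (r in unique(list(r1, r2))) {
        U <- c(U, r[1]); V <- c(V, r[2])
        M <- c(M, if (r[1] == r[2]) 1L else 2L)
        CLS <- c(CLS, jc)
      }
    }
  }
  list(U = U, V = V, M = M, CLS = CLS, n_class = KA * KB, n_hap = ka * kb, KB = KB)
}

# allele frequencies implied by genotype codes of one locus
code_allele_freqs <- function(code, k) {
  pt <- pair_table(k)
  cnt <- numeric(k)
  tab <- tabulate(code, nbins = nrow(pt))
  for (g in seq_len(nrow(pt))) {
    cnt[pt[g, 1]] <- cnt[pt[g, 1]] + tab[g]
    cnt[pt[g, 2]] <- cnt[pt[g, 2]] + tab[g]
  }
  cnt / sum(cnt)
}

em_best_fit <- function(cnt, st, ea, eb, tol, max_iter, n_restarts, seed) {
  pa <- code_allele_freqs(ea$code, ea$k)
  pb <- code_allele_freqs(eb$code, eb$k)
  f0 <- rep(pa, each = eb$k) * rep(pb, times = ea$k)
  nz <- which(cnt > 0)
  keep <- st$CLS %in% nz
  env <- list(U = st$U[keep], V = st$V[keep], M = st$M[keep],
              cls = match(st$CLS[keep], nz), cnt = cnt[nz],
              n_cls = length(nz), n_hap = st$n_hap)
  logL_null <- em_loglik(f0, env)
  best <- em_run(f0, env, tol, max_iter)
  if (n_restarts > 1) {
    for (r in seq_len(n_restarts - 1L)) {
      f_r <- withr::with_seed(derive_seed(seed, r), {
        g <- stats::rgamma(st$n_hap, shape = 1)
        g / sum(g)
      })
      cand <- em_run(f_r, env, tol, max_iter)
      if (cand$logL > best$logL) best <- cand
    }
  }
  best$logL_null <- logL_null
  best
}

em_loglik <- function(f, env) {
  w <- env$M * f[env$U] * f[env$V]
  L <- numeric(env$n_cls)
  agg <- rowsum(w, env$cls)
  L[as.integer(rownames(agg))] <- agg[, 1]
  if (any(L <= 0)) return(-Inf)
  sum(env$cnt * log(L))
}

em_run <- function(f, env, tol, max_iter) {
  ntot <- sum(env$cnt)
  ll <- em_loglik(f, env)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- env$M * f[env$U] * f[env$V]
    L <- numeric(env$n_cls)
    agg <- rowsum(w, env$cls)
    L[as.integer(rownames(agg))] <- agg[, 1]
    share <- env$cnt[env$cls] * w / L[env$cls]
    e <- numeric(env$n_hap)
    agg2 <- rowsum(c(share, share), c(env$U, env$V))
    e[as.integer(rownames(agg2))] <- agg2[, 1]
    f_new <- e / (2 * ntot)
    ll_new <- em_loglik(f_new, env)
    # EM is a majorization scheme: the log-likelihood may never decrease
    abort_if(ll_new < ll - 1e-7, "EM log-likelihood decreased; numerical failure")
    f <- f_new
    if (ll_new - ll < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(f = f, logL = ll, n_iter = iter, converged = converged)
}
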