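# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Levene conditional pmf via the multinomial/binomial identity:
# P(h | n_a) = dmultinom((n_a-h)/2, h, (n_b-h)/2 ; HWE probs) / dbinom(n_a; 2n, p)
oracle_levene_pmf <- function(n_a, n) {
  n_b <- 2 * n - n_a
  p <- n_a / (2 * n)
  h <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  vapply(h, function(hh) {
    stats::dmultinom(c((n_a - hh) / 2, hh, (n_b - hh) / 2),
                     prob = c(p^2, 2 * p * (1 - p), (1 - p)^2)) /
      stats::dbinom(n_a, 2 * n, p)
  }, numeric(1)) |> stats::setNames(h)
}

# brute-force exact HWE p-value for tiny samples: enumerate every perfect
# pairing of the 2n labelled alleles and tabulate heterozygote counts
oracle_hwe_tiny <- function(n_dd, n_di, n_ii) {
  n <- n_dd + n_di + n_ii
  alleles <- rep(c(0L, 1L), times = c(2 * n_dd + n_di, 2 * n_ii + n_di))
  pairings <- function(items) {
    if (length(items) == 0) return(list(integer(0)))
    first <- items[1]
    out <- list()
    for (k in seq_along(items)[-1]) {
      rest <- pairings(items[-c(1, k)])
      out <- c(out, lapply(rest, function(r) c(first, items[k], r)))
    }
    out
  }
  hets <- vapply(pairings(seq_along(alleles)), function(ord) {
    a <- alleles[ord]
    sum(a[seq(1, length(a), 2)] != a[seq(2, length(a), 2)])
  }, integer(1))
  tab <- table(hets) / length(hets)
  p_obs <- tab[[as.character(n_di)]]
  sum(tab[tab <= p_obs + 1e-12])
}

# two-locus genotype-class log-likelihood under random union of gametes,
# written from scratch over ordered haplotype pairs (2x2 alleles)
oracle_two_locus_loglik <- function(joint_counts, f) {
  # joint_counts: 3x3 matrix, rows genotype at A (DD, DI, II), cols at B
  # f: haplotype freqs in order (D-D, D-I, I-D, I-I)
  hapA <- c(1, 1, 2, 2)  # locus-A allele of each haplotype (1 = D, 2 = I)
  hapB <- c(1, 2, 1, 2)
  geno_prob <- matrix(0, 3, 3)
  for (u in 1:4) for (v in 1:4) {
    ga <- hapA[u] + hapA[v] - 1  # 1=DD, 2=DI, 3=II
    gb <- hapB[u] + hapB[v] - 1
    geno_prob[ga, gb] <- geno_prob[ga, gb] + f[u] * f[v]
  }
  if (any(geno_prob[joint_counts > 0] <= 0)) return(-Inf)
  sum(joint_counts[joint_counts > 0] * log(geno_prob[joint_counts > 0]))
}

# brute-force maximum of the two-locus likelihood over the 3-simplex,
# multi-start Nelder-Mead on softmax-transformed parameters
oracle_two_locus_ml <- function(joint_counts, n_starts = 25, seed = 1) {
  obj <- function(theta) {
    f <- exp(c(theta, 0)); f <- f / sum(f)
    -oracle_two_locus_loglik(joint_counts, f)
  }
  best <- Inf
  withr::with_seed(seed, {
    for (s in seq_len(n_starts)) {
      th0 <- stats::rnorm(3, sd = 2)
      fit <- try(stats::optim(th0, obj, method = "Nelder-Mead",
                              control = list(maxit = 5000, reltol = 1e-14)),
                 silent = TRUE)
      if (!inherits(fit, "try-error") && fit$value < best) best <- fit$value
    }
  })
  -best
}

# joint genotype counts (3x3) from two biallelic call vectors
joint_counts_3x3 <- function(a, b) {
  lev <- c("D/D", "D/I", "I/I")
  table(factor(a, levels = lev), factor(b, levels = lev))
}

# random additive tree and its exact leaf-to-leaf distance matrix
random_additive_tree <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) stats::runif(k, 0.5, 3))
    tr$tip.label <- sort(tr$tip.label)  # stable labels A-like ordering
    d <- ape::cophenetic.phylo(tr)
    list(tree = tr, d = d[order(rownames(d)), order(colnames(d))])
  })
}
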