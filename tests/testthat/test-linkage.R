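test_that("Bonferroni thresholds match the standard families", {
  expect_equal(signif(bonferroni_alpha(0.05, 30), 3), 0.00167)
  expect_equal(bonferroni_alpha(0.05, 435), 0.05 / 435, tolerance = 1e-12)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_error(bonferroni_alpha(0.05, 0), "m must")
})

test_that("complete association yields the two coupling haplotypes", {
  a <- rep(c("D/D", "I/I"), each = 50)
  fit <- em_haplotypes(a, a)
  hap <- dplyr::arrange(fit$haplotypes, allele_a, allele_b)
  expect_equal(hap$freq, c(0.5, 0, 0, 0.5), tolerance = 1e-9)
  expect_gt(fit$logL, fit$logL_null)
})

test_that("a monomorphic partner forces product-structure haplotypes", {
  a <- c("D/D", "D/I", "I/I", "D/I")
  b <- rep("D/D", 4)
  fit <- em_haplotypes(a, b)
  expect_equal(fit$haplotypes$freq, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(fit$logL, fit$logL_null, tolerance = 1e-9)
})

test_that("EM log-likelihood dominates the independence null", {
  for (seed in 1:10) {
    g <- simulate_hwe_genotypes(c(A = 0.3, B = 0.7), n = 60, seed = seed)
    fit <- em_haplotypes(g$A, g$B)
    expect_gte(fit$logL, fit$logL_null - 1e-9)
    expect_true(fit$converged)
    expect_equal(sum(fit$haplotypes$freq), 1, tolerance = 1e-9)
  }
})

test_that("EM attains the brute-force maximum likelihood on small instances", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(8:30, 1)
    qa <- runif(1, 0.2, 0.8); qb <- runif(1, 0.2, 0.8)
    g <- simulate_hwe_genotypes(c(A = qa, B = qb), n = n, seed = 100 + i)
    fit <- em_haplotypes(g$A, g$B, tol = 1e-12, max_iter = 5000)
    jc <- joint_counts_3x3(g$A, g$B)
    want <- oracle_two_locus_ml(jc, seed = i)
    expect_lt(abs(fit$logL - want), 1e-6)
  }
})

test_that("the LR permutation test nails complete association and ignores monomorphism", {
  tbl <- tibble::tibble(sample_id = paste0("S", 1:100),
                        A = rep(c("D/D", "I/I"), each = 50),
                        B = rep(c("D/D", "I/I"), each = 50),
                        M = rep("D/D", 100))
  hit <- ld_test(tbl, "A", "B", n_perm = 1000, seed = 3)
  expect_gt(hit$lr_stat, 0)
  expect_lte(hit$p_perm, 0.01)

  mono <- ld_test(tbl, "A", "M", n_perm = 100, seed = 3)
  expect_equal(mono$lr_stat, 0, tolerance = 1e-9)
  expect_equal(mono$p_perm, 1)
})

test_that("LD results are reproducible under a fixed master seed", {
  g <- simulate_hwe_genotypes(c(A = 0.4, B = 0.5, C = 0.6), n = 80, seed = 12)
  r1 <- ld_all_pairs(g, n_perm = 99, seed = 7)
  r2 <- ld_all_pairs(g, n_perm = 99, seed = 7)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 3)  # C(3, 2)
  expect_named(r1, c("locus_a", "locus_b", "lr_stat", "p_perm", "n_perm",
                     "seed", "significant"))
})

test_that("pair enumeration follows C(L, 2)", {
  g2 <- simulate_hwe_genotypes(c(A = 0.4, B = 0.5), n = 30, seed = 1)
  expect_equal(nrow(ld_all_pairs(g2, n_perm = 19, seed = 1)), 1)
  g5 <- simulate_hwe_genotypes(stats::setNames(rep(0.5, 5), paste0("L", 1:5)),
                               n = 30, seed = 2)
  expect_equal(nrow(ld_all_pairs(g5, n_perm = 19, seed = 1)), 10)
})

test_that("mixed STR x InDel pairs run through the multiallelic EM path", {
  n <- 120
  str_freqs <- c(`8` = 0.2, `9` = 0.3, `10` = 0.25, `11` = 0.25)
  tbl <- tibble::tibble(
    sample_id = paste0("S", seq_len(n)),
    CSF1PO = simulate_multiallelic_locus(str_freqs, n, seed = 5),
    HLD67 = simulate_hwe_genotypes(c(HLD67 = 0.6046), n, seed = 6)$HLD67)
  res <- ld_test(tbl, "CSF1PO", "HLD67", n_perm = 99, seed = 4)
  expect_true(res$p_perm > 0 && res$p_perm <= 1)
  expect_gte(res$lr_stat, 0)
  hap <- attr(res, "haplotypes")
  expect_equal(nrow(hap), 8)  # 4 STR alleles x 2 InDel alleles
  expect_equal(sum(hap$freq), 1, tolerance = 1e-9)
})
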