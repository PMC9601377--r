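test_that("generators are bit-reproducible and emit valid tables", {
  freqs <- c(L1 = 0.3, L2 = 0.5, L3 = 0.8)
  g1 <- simulate_hwe_genotypes(freqs, n = 50, seed = 77)
  g2 <- simulate_hwe_genotypes(freqs, n = 50, seed = 77)
  expect_identical(g1, g2)
  expect_silent(validate_genotypes(g1))

  bn1 <- simulate_balding_nichols(freqs, 0.1, 2, sizes = 40, seed = 9)
  bn2 <- simulate_balding_nichols(freqs, 0.1, 2, sizes = 40, seed = 9)
  expect_identical(bn1, bn2)
  expect_silent(validate_genotypes(bn1$genotypes))

  c1 <- simulate_multiallelic_locus(c(`8` = 0.5, `9` = 0.5), 30, seed = 3)
  expect_identical(c1, simulate_multiallelic_locus(c(`8` = 0.5, `9` = 0.5), 30, seed = 3))
})

test_that("fixed alleles produce uniform homozygotes", {
  g <- simulate_hwe_genotypes(c(L1 = 1, L2 = 0), n = 25, seed = 2)
  expect_true(all(g$L1 == "I/I"))
  expect_true(all(g$L2 == "D/D"))
})

test_that("observed heterozygosity converges at the binomial rate", {
  g <- simulate_hwe_genotypes(c(L1 = 0.5), n = 10000, seed = 5)
  h <- count_genotypes(g)
  expect_lt(abs(h$n_di / h$n - 0.5), 0.015)  # 3 sigma at n = 10000

  # c / sqrt(n) convergence of the allele-frequency estimate
  errs <- vapply(c(100, 1000, 10000), function(n) {
    cnt <- count_genotypes(simulate_hwe_genotypes(c(L1 = 0.35), n = n, seed = n))
    abs((2 * cnt$n_ii + cnt$n_di) / (2 * cnt$n) - 0.35)
  }, numeric(1))
  expect_true(all(errs < 3 * sqrt(0.35 * 0.65 / (2 * c(100, 1000, 10000)))))
})

test_that("inbreeding shifts genotype proportions as specified", {
  # heterozygosity should average 2pq(1 - fis) = 0.25; averaging over seeds
  # keeps the check well inside Monte-Carlo noise (SE ~ 0.001)
  hets <- vapply(1:10, function(s) {
    cnt <- count_genotypes(simulate_inbred_genotypes(c(L1 = 0.5), n = 20000,
                                                     fis = 0.5, seed = s))
    cnt$n_di / cnt$n
  }, numeric(1))
  expect_lt(abs(mean(hets) - 0.25), 0.004)
  g99 <- simulate_inbred_genotypes(c(L1 = 0.5), n = 5000, fis = 0.99, seed = 14)
  expect_lt(count_genotypes(g99)$n_di / 5000, 0.02)
})

test_that("inbreeding at fis = 0.5 is detected by the exact HWE test with high power", {
  rejections <- vapply(1:200, function(i) {
    g <- simulate_inbred_genotypes(c(L1 = 0.5), n = 631, fis = 0.5, seed = 5000 + i)
    cnt <- count_genotypes(g)
    hwe_exact_p(cnt$n_dd, cnt$n_di, cnt$n_ii) < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.99)
})

test_that("Balding-Nichols frequencies concentrate on the ancestor as F -> 0", {
  anc <- c(L1 = 0.4, L2 = 0.6)
  sim <- simulate_balding_nichols(anc, 0.0005, 5, sizes = 10, seed = 8)
  ins <- dplyr::filter(sim$frequencies, allele == "I")
  expect_lt(max(abs(ins$freq - anc[ins$locus])), 0.06)
})

test_that("Balding-Nichols reduces across-population heterozygosity by 1 - F", {
  F <- 0.1
  anc <- stats::setNames(runif(1000, 0.2, 0.8), paste0("L", 1:1000))
  set.seed(1)
  sim <- simulate_balding_nichols(anc, F, 1, sizes = 2, seed = 15)
  ins <- dplyr::filter(sim$frequencies, allele == "I")
  ratio <- mean(2 * ins$freq * (1 - ins$freq)) / mean(2 * anc * (1 - anc))
  expect_equal(ratio, 1 - F, tolerance = 0.02)
})

test_that("multiallelic simulation reaches its configured gene diversity", {
  freqs <- stats::setNames(rep(0.1, 10), as.character(6:15))
  col <- simulate_multiallelic_locus(freqs, n = 10000, seed = 23)
  parts <- strsplit(col, "/", fixed = TRUE)
  het <- mean(vapply(parts, function(p) p[1] != p[2], logical(1)))
  expect_equal(het, 0.9, tolerance = 0.01)
})

test_that("the study-like default reproduces the design: 631 samples, 30 loci, 3 regions", {
  g <- simulate_reference_panel(seed = 3)
  expect_equal(nrow(g), 631)
  expect_equal(length(setdiff(names(g), c("sample_id", "population"))), 30)
  expect_equal(sort(unique(g$population)), sort(c("Bialystok", "Poznan", "Warsaw")))
  expect_equal(range(table(g$population)), c(210, 211))
})
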