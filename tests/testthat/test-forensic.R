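test_that("PIC matches published values and closed-form anchors", {
  expect_equal(round(pic(c(0.4422, 0.5578)), 4), 0.3716)
  expect_equal(pic(c(0.5, 0.5)), 0.375)       # biallelic maximum
  expect_equal(pic(c(1, 0)), 0)
})

test_that("match probability / PD work on observed genotype proportions", {
  expect_equal(round(power_of_discrimination(c(153, 288, 190)), 4), 0.6422)
  expect_equal(match_probability(c(10, 0, 0)), 1)
  expect_equal(match_probability(c(7, 7, 0)), 0.5)
  cnt <- c(153, 288, 190)
  expect_identical(match_probability(cnt) + power_of_discrimination(cnt), 1)
})

test_that("PE and TPI reproduce published anchors and behave at the edges", {
  h93 <- 343 / 631
  expect_equal(round(power_of_exclusion(h93), 4), 0.2286)
  expect_equal(round(typical_paternity_index(h93), 4), 1.0955)
  expect_equal(power_of_exclusion(0), 0)
  expect_equal(power_of_exclusion(1), 1)
  expect_equal(typical_paternity_index(0.5), 1)
  expect_equal(typical_paternity_index(0), 0.5)
  expect_error(typical_paternity_index(1), "infinite")
})

test_that("unbiased expected heterozygosity carries the 2n/(2n-1) correction", {
  expect_equal(round(unbiased_expected_heterozygosity(c(0.3352, 0.6648), 631), 4), 0.4460)
  expect_equal(unbiased_expected_heterozygosity(c(0.5, 0.5), 1e9), 0.5, tolerance = 1e-8)
  expect_equal(unbiased_expected_heterozygosity(c(1, 0), 50), 0)
})

test_that("PIC stays strictly below gene diversity for polymorphic loci", {
  set.seed(7)
  for (i in 1:50) {
    p <- runif(1, 0.01, 0.99)
    expect_lt(pic(c(p, 1 - p)), 1 - p^2 - (1 - p)^2)
  }
})

test_that("PE and TPI are increasing in observed heterozygosity", {
  h <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(power_of_exclusion(h)) > 0))
  expect_true(all(diff(typical_paternity_index(h)) > 0))
})

test_that("combined indexes multiply correctly", {
  loci <- tibble::tibble(pm = c(0.5, 0.5), pe = c(0.5, 0.5))
  got <- combined_indexes(loci)
  expect_equal(got$cpm, 0.25)
  expect_equal(got$cpd, 0.75)
  expect_equal(got$cpe, 0.75)
  expect_identical(got$cpd, 1 - got$cpm)
})

test_that("panel summaries are invariant to sample order and flag empty loci", {
  g <- simulate_hwe_genotypes(c(L1 = 0.4, L2 = 0.6), n = 40, seed = 2)
  s1 <- summarize_panel(g)
  s2 <- summarize_panel(g[rev(seq_len(nrow(g))), ])
  expect_equal(tidy(s1), tidy(s2))

  g$L1 <- NA_character_
  expect_error(summarize_panel(g), "L1")
})

test_that("monomorphic panels have zero combined discrimination power", {
  g <- tibble::tibble(sample_id = paste0("S", 1:10),
                      L1 = rep("D/D", 10), L2 = rep("I/I", 10))
  s <- summarize_panel(g)
  expect_equal(glance(s)$cpd, 0)
  expect_equal(glance(s)$cpm, 1)
})

test_that("panel report writes published-style 4-decimal columns", {
  counts <- reconstruct_counts(suppressMessages(load_dipplex_panel()))[1:3, ]
  s <- summarize_counts(counts)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_report(s, path)
  rep <- readr::read_csv(path, show_col_types = FALSE)
  expect_named(rep, c("locus", "freq_del", "freq_ins", "het_obs", "het_exp",
                      "p_hwe", "pic", "pd", "pe", "tpi"))
  expect_equal(rep$pic, round(tidy(s)$pic, 4))
})
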