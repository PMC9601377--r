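additive_example <- function() {
  labs <- c("A", "B", "C", "D")
  matrix(c(0, 5, 7, 8,
           5, 0, 8, 9,
           7, 8, 0, 9,
           8, 9, 9, 0), 4, 4, dimnames = list(labs, labs))
}

test_that("neighbor joining recovers the canonical additive quartet exactly", {
  d <- additive_example()
  # four-point condition confirms the matrix is additive before the NJ check
  sums <- c(d["A", "B"] + d["C", "D"], d["A", "C"] + d["B", "D"],
            d["A", "D"] + d["B", "C"])
  expect_equal(sort(sums)[2], sort(sums)[3])
  tr <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  nwk <- to_newick(tr)
  expect_match(nwk, "\\(A:2\\.000000,B:3\\.000000\\)")
  expect_match(nwk, "C:4\\.000000")
  expect_match(nwk, "D:5\\.000000")
})

test_that("three taxa solve the path equations in closed form", {
  labs <- c("X", "Y", "Z")
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3, dimnames = list(labs, labs))
  tr <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tr)[labs, labs], d, tolerance = 1e-12)
  expect_equal(sort(tr$edge.length), c(1, 2, 3))
})

test_that("taxon order does not change the unrooted topology or lengths", {
  d <- additive_example()
  perm <- c("C", "A", "D", "B")
  t1 <- nj_tree(d)
  t2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0)
  expect_equal(ape::cophenetic.phylo(t2)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
})

test_that("random additive trees are recovered exactly (4-12 taxa)", {
  for (seed in 1:12) {
    n_taxa <- 4 + (seed %% 9)
    ref <- random_additive_tree(n_taxa, seed)
    tr <- nj_tree(ref$d)
    expect_equal(ape::dist.topo(ape::unroot(ref$tree), tr)[1], 0)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(ref$d), colnames(ref$d)],
                 ref$d, tolerance = 1e-8)
    # independent cross-check against the reference NJ implementation
    expect_equal(ape::dist.topo(ape::nj(ref$d), tr)[1], 0)
  }
})

test_that("branch lengths are never negative on noisy matrices", {
  for (seed in 1:5) {
    ref <- random_additive_tree(7, 100 + seed)
    noisy <- ref$d + withr::with_seed(seed, {
      e <- matrix(stats::runif(49, 0, 0.4), 7, 7)
      e <- (e + t(e)) / 2; diag(e) <- 0; e
    })
    tr <- nj_tree(noisy)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("newick serialisation round-trips and orders children deterministically", {
  ref <- random_additive_tree(8, 5)
  tr <- nj_tree(ref$d)
  nwk <- to_newick(tr)
  back <- ape::read.tree(text = nwk)
  expect_equal(ape::dist.topo(back, tr)[1], 0)
  expect_equal(ape::cophenetic.phylo(back)[ref$tree$tip.label, ref$tree$tip.label],
               ape::cophenetic.phylo(tr)[ref$tree$tip.label, ref$tree$tip.label],
               tolerance = 1e-6)
  perm <- rev(rownames(ref$d))
  expect_identical(to_newick(nj_tree(ref$d[perm, perm])), nwk)

  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  expect_identical(readLines(path), nwk)
})

test_that("degenerate distance inputs are rejected", {
  d <- additive_example()
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  d[1, 2] <- d[2, 1] <- Inf
  expect_error(nj_tree(d), "non-finite")
})

test_that("planar configurations embed with zero stress", {
  labs <- c("P", "Q", "R")
  tri <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3, dimnames = list(labs, labs))
  expect_lt(mds_smacof(tri)$stress, 1e-6)

  line <- abs(outer(1:4, 1:4, `-`)) * 1.5
  dimnames(line) <- list(letters[1:4], letters[1:4])
  expect_lt(mds_smacof(line)$stress, 1e-6)
})

test_that("stress never increases across majorization steps", {
  ref <- random_additive_tree(10, 9)
  fit <- mds_smacof(ref$d)
  expect_true(all(diff(fit$stress_trace) <= 1e-9))
  expect_gte(fit$stress, 0)
  expect_equal(colMeans(fit$points), c(dim1 = 0, dim2 = 0), tolerance = 1e-9)
})

test_that("the deterministic Torgerson start makes repeated fits identical", {
  m <- load_worldwide_fst()
  f1 <- mds_smacof(m)
  f2 <- mds_smacof(m)
  expect_identical(f1$points, f2$points)
  expect_identical(tidy(f1)$label, rownames(m))
})

test_that("an all-zero matrix collapses to the origin with zero stress", {
  z <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  fit <- mds_smacof(z)
  expect_equal(unname(fit$points), matrix(0, 3, 2))
  expect_equal(fit$stress, 0)
})

test_that("mds coordinates export with a stress header", {
  fit <- mds_smacof(load_worldwide_fst())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mds_coords(fit, path)
  lines <- readLines(path)
  expect_match(lines[1], "stress-1")
  expect_equal(length(lines), 22)  # comment + header + 20 rows
})
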