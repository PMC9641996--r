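# Matched-pairs symmetry tests: exact small examples, algebraic identities,
# and the structural behaviour of the cluster-level screen.

test_that("paired_site_counts: diagonal, totals, transposition", {
  aln <- rbind(a = c("A", "C", "G", "T", "A", "C"),
               b = c("A", "C", "G", "T", "A", "C"),
               c = c("A", "G", "G", "-", "A", "T"))
  pc <- paired_site_counts(aln, "a", "b", positions = 1:3)
  expect_true(all(pc$n[upper.tri(pc$n)] == 0) &&
                all(pc$n[lower.tri(pc$n)] == 0))
  expect_equal(pc$total, 6L)
  pac <- paired_site_counts(aln, "a", "c", positions = 1:3)
  expect_equal(pac$total, 5L)                   # gap column excluded
  pca <- paired_site_counts(aln, "c", "a", positions = 1:3)
  expect_identical(pca$n, t(pac$n))
  # position restriction: only codon positions 1+2 of the 6 columns
  p12 <- paired_site_counts(aln, "a", "b", positions = c(1, 2))
  expect_equal(p12$total, 4L)
  expect_error(paired_site_counts(aln, "a", "zz"), "absent")
})

test_that("bowker_test exact values", {
  sym <- matrix(c(10, 3, 0, 0, 3, 9, 1, 0, 0, 1, 8, 2, 0, 0, 2, 7), 4, 4)
  b <- bowker_test(sym)
  expect_equal(b$stat, 0)
  expect_equal(b$p, 1)
  # single off-diagonal pair n_AG=10, n_GA=2
  n <- diag(c(5, 5, 5, 5)); n[1, 3] <- 10; n[3, 1] <- 2
  b2 <- bowker_test(n)
  expect_equal(b2$stat, 64 / 12, tolerance = 1e-12)
  expect_equal(b2$df, 1L)
  expect_equal(b2$p, pchisq(64 / 12, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(b2$p, 4), 0.0209)
  # purely diagonal matrix: df 0, p 1
  b3 <- bowker_test(diag(c(4, 3, 2, 1)))
  expect_equal(b3$df, 0L)
  expect_equal(b3$p, 1)
})

test_that("stuart_test matches the explicit 3x3 solve and detects marginals only", {
  n <- matrix(c(50, 10, 3, 2, 2, 60, 4, 1, 5, 6, 70, 3, 1, 2, 3, 80), 4, 4,
              byrow = TRUE)
  s <- stuart_test(n)
  u <- (rowSums(n) - colSums(n))[1:3]
  V <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    V[i, j] <- if (i == j) rowSums(n)[i] + colSums(n)[i] - 2 * n[i, i]
  else -(n[i, j] + n[j, i])
  expect_equal(s$stat, drop(t(u) %*% solve(V) %*% u), tolerance = 1e-12)
  expect_equal(s$df, 3L)

  # symmetric matrix: u = 0, stat 0
  sym <- matrix(c(10, 3, 1, 0, 3, 9, 1, 0, 1, 1, 8, 2, 0, 0, 2, 7), 4, 4)
  expect_equal(stuart_test(sym)$stat, 0)

  # marginally symmetric but internally asymmetric (a 3-cycle):
  # row sums equal column sums, yet n_ij != n_ji
  cyc <- diag(c(20, 20, 20, 20))
  cyc[1, 2] <- 5; cyc[2, 3] <- 5; cyc[3, 1] <- 5
  cyc[2, 1] <- 1; cyc[3, 2] <- 1; cyc[1, 3] <- 1
  cyc[1, 4] <- cyc[4, 1] <- 4                   # symmetric T interactions
  cyc[2, 4] <- cyc[4, 2] <- 3                   # keep V invertible without
  cyc[3, 4] <- cyc[4, 3] <- 2                   # touching marginal symmetry
  expect_equal(rowSums(cyc), colSums(cyc))
  sc <- stuart_test(cyc)
  bc <- bowker_test(cyc)
  expect_lt(sc$stat, 1e-9)
  expect_gt(bc$stat, 1)

  # degenerate: all-zero table -> singular V, flagged, p = 1
  sd0 <- stuart_test(matrix(0L, 4, 4))
  expect_true(sd0$degenerate)
  expect_equal(sd0$p, 1)
})

test_that("internal symmetry test: identity and chi-square oracle", {
  n <- matrix(c(30, 8, 2, 1, 4, 25, 6, 2, 5, 3, 28, 7, 2, 4, 3, 22), 4, 4,
              byrow = TRUE)
  b <- bowker_test(n); s <- stuart_test(n); i <- internal_symmetry_test(n)
  expect_equal(i$stat + s$stat, b$stat, tolerance = 1e-9)
  expect_equal(i$df, b$df - 3L)
  expect_equal(i$p, pchisq(b$stat - s$stat, b$df - 3, lower.tail = FALSE),
               tolerance = 1e-12)
  # symmetric input: everything 0 / p 1
  sym <- matrix(c(10, 3, 1, 2, 3, 9, 1, 4, 1, 1, 8, 2, 2, 4, 2, 7), 4, 4)
  expect_equal(internal_symmetry_test(sym)$stat, 0)
  expect_equal(internal_symmetry_test(sym)$p, 1)
})

test_that("stat invariants hold on random tables", {
  set.seed(14)
  for (i in 1:50) {
    n <- matrix(rpois(16, lambda = sample(c(2, 10, 40), 1)), 4, 4)
    b <- bowker_test(n); s <- stuart_test(n); int <- internal_symmetry_test(n)
    expect_identical(bowker_test(t(n))$stat, b$stat)
    expect_gte(b$stat, 0)
    if (!s$degenerate) expect_lte(s$stat, b$stat + 1e-9)
    if (!is.na(int$stat)) expect_gte(int$stat, 0)
  }
})

test_that("srh_filter_cluster verdicts", {
  aln <- matrix("A", 4, 30, dimnames = list(paste0("t", 1:4), NULL))
  r <- srh_filter_cluster(aln)
  expect_equal(r$verdict, "pass")               # identical sequences
  expect_equal(nrow(r$pairs), 6L)
  expect_error(srh_filter_cluster(aln[1, , drop = FALSE]), ">= 2 taxa")
})
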