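# TPM normalization, fold-changes, the Audic-Claverie test and calls.

test_that("TPM normalization matches the definition on the printed counts", {
  expect_identical(tpm(5, 1e6), 5)
  expect_identical(tpm(0, 12345), 0)
  # the most abundant conserved family member: 384,671 of 7,655,306 reads
  expect_equal(tpm(384671, 7655306), 50249.04, tolerance = 0.5)
  expect_error(tpm(1, 0), "> 0")
})

test_that("log2 fold-change handles zeros through the pseudo-TPM", {
  expect_identical(log2FoldChange(8, 2, pseudo = 0), 2)
  expect_identical(log2FoldChange(7.3, 7.3), 0)
  expect_equal(log2FoldChange(0, 10, pseudo = 0.01), log2(0.01 / 10.01),
               tolerance = 1e-12)
})

test_that("point probabilities match closed forms on small counts", {
  # x = 0, y = 0, equal libraries: p = 1/2
  expect_equal(acPvalue(0, 0, 1e6, 1e6)$p_point, 0.5, tolerance = 1e-12)
  # x = 2, y = 1, equal libraries: 3!/(2! 1! 2^4)
  expect_equal(acPvalue(2, 1, 1e6, 1e6)$p_point, 0.1875, tolerance = 1e-12)
  expect_error(acPvalue(-1, 0, 1e6, 1e6), "nonnegative")
})

test_that("log-space tails agree with the recurrence oracle and pnbinom", {
  for (r in c(0.5, 1, 2)) {
    N1 <- 1e6; N2 <- r * 1e6
    for (x in c(0, 3, 17, 60)) {
      y <- 0:80
      got <- acPvalue(rep(x, length(y)), y, N1, N2)
      p <- oracleAcDist(x, max(y), N1, N2)
      expect_equal(got$p_point, p[y + 1], tolerance = 1e-10)
      expect_equal(got$C, cumsum(p)[y + 1], tolerance = 1e-10)
      # the conditional distribution is negative binomial: independent
      # cross-check through base R
      expect_equal(got$C, stats::pnbinom(y, size = x + 1,
                                         prob = N1 / (N1 + N2)),
                   tolerance = 1e-10)
    }
  }
})

test_that("the conditional distribution is normalized and C + D - p == 1", {
  for (r in c(0.5, 1, 2)) {
    for (x in c(0, 5, 20)) {
      p <- oracleAcDist(x, 5000, 1e6, r * 1e6)
      expect_equal(sum(p), 1, tolerance = 1e-9)
    }
  }
  res <- acPvalue(c(0, 4, 33, 250), c(7, 0, 40, 260), 2e6, 3e6)
  expect_equal(res$C + res$D - res$p_point, rep(1, 4), tolerance = 1e-9)
  expect_true(all(res$p_two_sided >= 0 & res$p_two_sided <= 1))
})

test_that("library swap negates the fold-change and rescales the point formula", {
  set.seed(31)
  x <- rpois(50, 40); y <- rpois(50, 70)
  N1 <- 2e6; N2 <- 5e6
  a <- acPvalue(x, y, N1, N2)
  b <- acPvalue(y, x, N2, N1)
  # exact identity of the printed formula:
  # p(x | y; N2, N1) = (N2/N1) p(y | x; N1, N2)
  expect_equal(b$p_point, a$p_point * N2 / N1, tolerance = 1e-9)
  # equal library sizes make the point probability fully symmetric
  a1 <- acPvalue(x, y, 1e6, 1e6); b1 <- acPvalue(y, x, 1e6, 1e6)
  expect_equal(a1$p_point, b1$p_point, tolerance = 1e-12)
  # the test conditions on the first library, so the tails are not
  # exactly exchangeable; the evidence ordering must agree though
  expect_gt(stats::cor(log(a$p_two_sided), log(b$p_two_sided)), 0.999)
  expect_equal(log2FoldChange(tpm(y, N2), tpm(x, N1)),
               -log2FoldChange(tpm(x, N1), tpm(y, N2)), tolerance = 1e-12)
})

test_that("BH adjustment matches the hand computation", {
  expect_identical(adjustPvalues(0.004), 0.004)
  expect_equal(adjustPvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_identical(adjustPvalues(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.04)
  expect_true(all(adjustPvalues(p) >= p))
})

test_that("significance requires both strict thresholds", {
  res <- data.frame(p_adjusted = c(0.005, 0.005, 0.02, 0.005),
                    log2fc = c(1.5, 1.0, 3, -1.2))
  out <- callDE(res)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(out$direction, c("up", "up", "up", "down"))
})

test_that("the full table pipeline wires counts through to calls", {
  counts <- data.frame(id = c("a", "b", "c"),
                       x = c(1000L, 50L, 0L), y = c(4000L, 52L, 30L),
                       stringsAsFactors = FALSE)
  de <- diffExpression(counts, 1e6, 1e6)
  expect_identical(de$significant, c(TRUE, FALSE, TRUE))
  expect_identical(de$direction[1], "up")
  expect_equal(de$tpm_ck, counts$x, tolerance = 1e-12)
  expect_true(all(de$p_adjusted >= de$p_two_sided - 1e-12))
})
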