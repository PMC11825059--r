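test_that("accuracy is the exact-match fraction", {
  expect_equal(accuracyScore(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(accuracyScore(c(1, 2, 3), c(3, 1, 2)), 0.0)
  expect_equal(accuracyScore(c(0, 1, 0, 1), c(0, 1, 0, 0)), 0.75)
  expect_error(accuracyScore(1:3, 1:4), "equal length")
})

test_that("pairwise wins are antisymmetric and missing-aware", {
  tb <- matrix(c(0.9, 0.5, 0.7, NA,
                 0.8, 0.5, 0.9, 0.6,
                 0.1, 0.2, 0.3, 0.4), 4, 3,
               dimnames = list(paste0("d", 1:4), c("A", "B", "C")))
  ab <- pairwiseWins(tb, "A", "B")
  ba <- pairwiseWins(tb, "B", "A")
  expect_equal(ab$wins, ba$losses)
  expect_equal(ab$losses, ba$wins)
  expect_equal(ab$ties, ba$ties)
  expect_equal(ab$excluded, "d4")
  expect_equal(ab$wins + ab$ties + ab$losses, 3)

  same <- pairwiseWins(cbind(tb[, c("A", "A")]), "A", "A")
  expect_equal(same$wins, 0)
  expect_equal(same$losses, 0)
  expect_error(pairwiseWins(tb, "A", "Z"), "unknown method")
})

test_that("Friedman ranks and statistic match brute force and stats::", {
  set.seed(10)
  tb <- matrix(runif(20), 5, 4,
               dimnames = list(paste0("d", 1:5), LETTERS[1:4]))
  out <- friedmanRankTest(tb)
  # independent brute-force rank-and-formula evaluation
  ranks <- matrix(0, 5, 4)
  for (i in 1:5) ranks[i, ] <- rank(-tb[i, ], ties.method = "average")
  Rj <- colSums(ranks)
  n <- 5; k <- 4
  stat <- ((k - 1) * sum((Rj - n * (k + 1) / 2)^2)) /
    (sum(ranks^2) - n * k * (k + 1)^2 / 4)
  expect_lt(abs(out$statistic - stat), 1e-10)
  expect_equal(out$meanRanks, setNames(Rj / n, LETTERS[1:4]))
  expect_equal(sum(ranks[1, ]), k * (k + 1) / 2)
  # tie-free tables agree with the base-R implementation
  ref <- stats::friedman.test(tb)
  expect_lt(abs(out$statistic - unname(ref$statistic)), 1e-10)
  expect_lt(abs(out$pValue - ref$p.value), 1e-10)
})

test_that("degenerate and dominant tables rank as expected", {
  same <- matrix(0.5, 4, 3, dimnames = list(paste0("d", 1:4), c("A", "B", "C")))
  out <- friedmanRankTest(same)
  expect_equal(out$statistic, 0)
  expect_equal(out$pValue, 1)

  dom <- matrix(runif(12, 0.1, 0.5), 4, 3,
                dimnames = list(paste0("d", 1:4), c("A", "B", "C")))
  dom[, 2] <- 0.9
  expect_equal(unname(friedmanRankTest(dom)$meanRanks[2]), 1)

  expect_error(friedmanRankTest(dom[, 1:2]), ">= 3 methods")
  expect_error(friedmanRankTest(dom[1, , drop = FALSE]), ">= 2")
})

test_that("one-sided-difference pairs attain the exact minimal p and are
           rejected by Holm", {
  set.seed(3)
  B <- runif(10, 0.4, 0.6)
  tb <- cbind(A = B + 0.01 * (1:10), B = B, C = runif(10))
  rownames(tb) <- paste0("d", 1:10)
  out <- wilcoxonHolm(tb, alpha = 0.05)
  # all ten differences positive and untied: p = 2 / 2^10
  expect_equal(out$pRaw["A", "B"], 2 / 1024, tolerance = 1e-12)
  expect_true(out$reject["A", "B"])
  # symmetry of the p matrices
  expect_equal(out$pRaw, t(out$pRaw))
  expect_equal(out$pHolm, t(out$pHolm))
})

test_that("Holm decisions are monotone in the raw p-values", {
  set.seed(8)
  tb <- matrix(runif(40), 8, 5,
               dimnames = list(paste0("d", 1:8), LETTERS[1:5]))
  out <- wilcoxonHolm(tb)
  ut <- upper.tri(out$pRaw)
  praw <- out$pRaw[ut]
  rej <- out$reject[ut]
  ord <- order(praw)
  # once a larger raw p is accepted, no even-larger p may be rejected
  expect_true(all(diff(as.integer(!rej[ord])) >= 0))
})

test_that("identical methods form one clique with p = 1 everywhere", {
  tb <- matrix(rep(runif(6), 3), 6, 3,
               dimnames = list(paste0("d", 1:6), c("A", "B", "C")))
  out <- wilcoxonHolm(tb)
  expect_true(all(out$pRaw[upper.tri(out$pRaw)] == 1))
  expect_false(any(out$reject))
  expect_length(out$cliques, 1L)
  expect_setequal(out$cliques[[1]], c("A", "B", "C"))
})

test_that("missing cells exclude rows from omnibus but not unrelated pairs", {
  tb <- matrix(runif(15), 5, 3,
               dimnames = list(paste0("d", 1:5), c("A", "B", "C")))
  tb[1, 3] <- NA
  fr <- friedmanRankTest(tb)
  expect_equal(fr$excluded, "d1")
  expect_equal(fr$nRows, 4)
  out <- wilcoxonHolm(tb)
  expect_length(out$excluded[["A vs B"]], 0L)
  expect_equal(out$excluded[["A vs C"]], "d1")
})
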