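test_that("bang blinding index covers the canonical tallies", {
  expect_equal(bang_blinding_index(0, 0, 100, boot_reps = 50)$index, 0)
  expect_equal(bang_blinding_index(40, 0, 0, boot_reps = 50)$index, 1)
  bi <- bang_blinding_index(30, 20, 50, seed = 4)
  expect_equal(bi$index, 0.10)
  expect_true(bi$lower <= 0.10 && bi$upper >= 0.10)
  # equal correct/incorrect guesses always give 0
  expect_equal(bang_blinding_index(17, 17, 3, boot_reps = 10)$index, 0)
  # seeded determinism
  expect_identical(bang_blinding_index(30, 20, 50, seed = 4),
                   bang_blinding_index(30, 20, 50, seed = 4))
})

test_that("cohens_kappa matches hand-computed agreement", {
  a <- rep(c("x", "y"), 25)
  expect_equal(cohens_kappa(a, a), 1)
  # 2x2 agreement table [[20,5],[10,15]]: po = 0.7, pe = 0.5, kappa = 0.4
  r1 <- c(rep("p", 25), rep("n", 25))
  r2 <- c(rep("p", 20), rep("n", 5), rep("p", 10), rep("n", 15))
  expect_equal(cohens_kappa(r1, r2), 0.4)
  # independent raters: kappa near 0
  set.seed(60)
  x <- sample(c("a", "b"), 1e4, replace = TRUE)
  y <- sample(c("a", "b"), 1e4, replace = TRUE)
  expect_lt(abs(cohens_kappa(x, y)), 0.05)
  # invariant under category relabelling
  expect_equal(cohens_kappa(chartr("pn", "qz", r1), chartr("pn", "qz", r2)),
               0.4)
})

test_that("fleiss_kappa matches the hand-evaluated estimator", {
  unanimous <- matrix(c(3, 0, 0, 3, 3, 0, 0, 3), ncol = 2, byrow = TRUE)
  expect_equal(fleiss_kappa(unanimous), 1)

  # 3 raters, 4 items, hand-built disagreement table
  m <- matrix(c(2, 1, 0,
                0, 3, 0,
                1, 1, 1,
                0, 0, 3), ncol = 3, byrow = TRUE)
  # hand: P_i = (sum n_ij^2 - 3) / 6 per item = (1/3, 1, 0, 1); Pbar = 7/12
  # p_j = (3, 5, 4) / 12; Pe = (9 + 25 + 16) / 144 = 50/144
  want <- (7 / 12 - 50 / 144) / (1 - 50 / 144)
  expect_equal(fleiss_kappa(m), want)

  # random ratings: kappa near 0
  set.seed(61)
  big <- t(replicate(4000, as.vector(rmultinom(1, 4, c(0.5, 0.5)))))
  expect_lt(abs(fleiss_kappa(big)), 0.05)
  expect_error(fleiss_kappa(matrix(c(2, 1, 3, 1), 2)), "same number")
})

test_that("two_proportion_diff has sane boundary and invariance behaviour", {
  eq <- two_proportion_diff(30, 100, 30, 100)
  expect_equal(eq$diff, 0)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  d12 <- two_proportion_diff(42, 757, 158, 762)
  d21 <- two_proportion_diff(158, 762, 42, 757)
  expect_equal(d21$diff, -d12$diff)
  expect_equal(d21$p, d12$p) # chi-square invariant under arm swap
  expect_true(d12$lower <= d12$diff && d12$diff <= d12$upper)
  # Newcombe interval also contains the difference
  nc <- two_proportion_diff(42, 757, 158, 762, method = "newcombe")
  expect_true(nc$lower <= nc$diff && nc$diff <= nc$upper)
})

test_that("welch_t matches the hand-evaluated Welch formula", {
  a <- c(6.0, 5.2, 7.1, 6.4, 5.8, 6.9)
  b <- c(8.1, 7.4, 9.0, 8.6, 11.2, 7.9, 8.4)
  res <- welch_t(a, b, tail = "less")
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  expect_equal(res$t, t_hand)
  expect_equal(res$df, df_hand)
  expect_equal(res$p, pt(t_hand, df_hand))
  # identical samples: t = 0, one-sided p = 0.5
  x <- c(1, 2, 3, 4)
  res0 <- welch_t(x, x, tail = "less")
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 0.5)
})

test_that("wilcoxon signed-rank: exact small-sample p-values", {
  # five all-positive differences, one-sided: p = 1/32
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), tail = "greater")
  expect_equal(res$p, 1 / 32)
  expect_true(res$exact)
  # symmetric pairs: p near the distribution centre
  sym <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3), tail = "greater")
  expect_gt(sym$p, 0.4)
  # zero differences are dropped
  expect_equal(wilcoxon_signed_rank(c(0, 0, 1, 2, 3, 4, 5),
                                    tail = "greater")$p, 1 / 32)
  expect_warning(z <- wilcoxon_signed_rank(c(0, 0)), "zero")
  expect_true(is.na(z$p))
})

test_that("wilcoxon exact p equals enumeration for every n <= 10, and matches wilcox.test", {
  set.seed(70)
  for (n in 2:10) {
    for (rep in 1:6) {
      d <- round(rnorm(n, 0.3, 1), 1)
      d <- d[d != 0]
      if (length(d) < 2) next
      for (tail in c("greater", "less", "two.sided")) {
        got <- wilcoxon_signed_rank(d, tail)$p
        expect_equal(got, signrank_p_oracle(d, tail), tolerance = 1e-12)
      }
      if (!any(duplicated(abs(d)))) {
        alt <- "greater"
        ref <- suppressWarnings(
          wilcox.test(d, alternative = alt, exact = TRUE)$p.value)
        expect_equal(wilcoxon_signed_rank(d, "greater")$p, ref,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("wilcoxon normal approximation is close to the exact distribution at n = 20", {
  set.seed(71)
  for (rep in 1:10) {
    d <- round(rnorm(20, 0.2, 1), 1)
    d <- d[d != 0]
    approx <- wilcoxon_signed_rank(d, "greater")
    expect_false(approx$exact)
    expect_lt(abs(approx$p - signrank_p_oracle(d, "greater")), 0.01)
  }
})

test_that("benjamini_hochberg applies the step-up rule", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(72)
  p <- runif(20)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
  expect_true(all(adj <= 1))
})

test_that("trial_report assembles blinding and comparison tables", {
  guesses <- data.frame(arm = c("AI", "reader"),
                        correct = c(210, 197), incorrect = c(205, 173),
                        dont_know = c(342, 392))
  outcomes <- data.frame(outcome = "initial_result_change",
                         x1 = 42, n1 = 757, x2 = 158, n2 = 762)
  rep <- trial_report(guesses, outcomes, seed = 3)
  expect_equal(nrow(rep$blinding), 2)
  expect_true(all(abs(rep$blinding$index) < 0.2))
  expect_equal(rep$comparisons$diff, 42 / 757 - 158 / 762)
})
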