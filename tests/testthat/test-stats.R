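test_that("exact Wilcoxon agrees with full enumeration and handles ties", {
  expect_equal(wilcoxon_rank_sum(1:3, 4:6, mode = "exact")$p, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  r <- wilcoxon_rank_sum(c(2, 2), c(2, 2))
  expect_true(r$degenerate)
  expect_equal(r$p, 1)
  # cross-check a tied small case against base R's exact machinery-free path
  x <- c(1.1, 2.3, 2.3, 4.0); y <- c(0.5, 2.3, 5.1)
  ours <- wilcoxon_rank_sum(x, y, mode = "exact")$p
  perm <- {
    pooled <- c(x, y); r <- rank(pooled)
    combs <- combn(7, 4)
    w <- colSums(matrix(r[combs], nrow = 4))
    mu <- mean(w)
    mean(abs(w - mu) >= abs(sum(r[1:4]) - mu) - 1e-9)
  }
  expect_equal(ours, perm)
})

test_that("normal-mode Wilcoxon matches the exact permutation law at n=30+30", {
  set.seed(41)
  x <- rnorm(30); y <- rnorm(30, 0.3)
  p_norm <- wilcoxon_rank_sum(x, y, mode = "normal")$p
  # Monte-Carlo permutation oracle
  pooled <- c(x, y); r <- rank(pooled)
  w_obs <- sum(r[1:30]); mu <- mean(r) * 30
  w_perm <- replicate(1e5, sum(sample(r, 30)))
  p_mc <- mean(abs(w_perm - mu) >= abs(w_obs - mu) - 1e-9)
  expect_lt(abs(p_norm - p_mc), 0.01)
  # and agrees with base R's continuity-corrected approximation
  p_base <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(p_norm, p_base, tolerance = 1e-10)
})

test_that("2x2 chi-squared matches a hand-rolled expected-count oracle", {
  tab <- matrix(c(14, 0, 77, 217), 2)  # group A: 14 EEP of 91; B: 0 of 217
  res <- chi2_2x2(tab)
  expect_lt(res$p, 0.001)
  expect_lt(chi2_2x2(tab, correction = TRUE)$p, 0.001)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  oracle <- sum((tab - expected)^2 / expected)
  expect_equal(res$statistic, oracle, tolerance = 1e-12)
  # perfect independence
  even <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(chi2_2x2(even)$statistic, 0)
  expect_equal(chi2_2x2(even)$p, 1)
  # zero margin is degenerate
  degen <- chi2_2x2(matrix(c(0, 0, 5, 7), 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
})

test_that("enrichment test switches between chi-squared and Fisher", {
  big <- enrichment_test(30, 100, 120, 500)
  expect_identical(big$method, "chi2")
  small <- enrichment_test(3, 4, 4, 8)
  expect_identical(small$method, "fisher")
  # Fisher two-sided p against direct hypergeometric summation
  res <- enrichment_test(3, 4, 4, 8)  # table [[3,1],[1,3]]
  probs <- dhyper(0:4, 4, 4, 4)
  obs <- dhyper(3, 4, 4, 4)
  oracle <- sum(probs[probs <= obs + 1e-12])
  expect_equal(res$p, oracle, tolerance = 1e-10)
  expect_equal(res$p, 0.4857, tolerance = 1e-4)
  expect_error(enrichment_test(5, 10, 3, 8), "contain the set")
})

test_that("Welch's t-test separates shifted groups and degrades gracefully", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$p, 1, tolerance = 1e-12)
  expect_lt(welch_t(c(1, 2, 3, 4), c(11, 12, 13, 14))$p, 0.01)
  degen <- welch_t(c(2, 2), c(2, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
})

test_that("Tukey HSD pairwise p-values follow the studentized-range law", {
  set.seed(13)
  groups <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  res <- anova_tukey(groups)
  # manual q statistic + studentized-range CDF for each pair
  n <- 8; k <- 3; df <- k * (n - 1)
  mse <- mean(vapply(groups, stats::var, numeric(1)))
  se <- sqrt(mse / n)
  for (row in seq_len(nrow(res$pairs))) {
    parts <- strsplit(res$pairs$comparison[row], "-")[[1]]
    q <- abs(mean(groups[[parts[1]]]) - mean(groups[[parts[2]]])) / se
    expect_equal(res$pairs$p_adj[row], 1 - stats::ptukey(q, k, df),
                 tolerance = 1e-3)
  }
  ident <- anova_tukey(list(a = c(1, 1), b = c(1, 1)))
  expect_true(ident$degenerate)
  expect_equal(ident$anova_p, 1)
})

test_that("p-value adjustment follows Bonferroni and BH step-up", {
  expect_equal(adjust_p(0.02, "bonferroni"), 0.02)
  expect_equal(adjust_p(0.02, "bh"), 0.02)
  expect_equal(adjust_p(c(0.01, 0.02, 0.03), "bh"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_p(rep(0.3, 5), "bonferroni"), rep(1, 5))
  # BH is monotone on sorted inputs
  set.seed(3)
  p <- sort(runif(50))
  expect_true(all(diff(adjust_p(p, "bh")) >= -1e-12))
})

test_that("wilcoxon type-I error is calibrated under a shared NB null", {
  set.seed(101)
  n_genes <- 1000
  p <- vapply(seq_len(n_genes), function(i) {
    x <- rnbinom(40, mu = 3, size = 2)
    y <- rnbinom(40, mu = 3, size = 2)
    wilcoxon_rank_sum(x, y, mode = "normal")$p
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("Pearson correlation matrix has the expected structure", {
  m <- rbind(s1 = c(1, 2, 3, 4), s2 = c(2, 4, 6, 8), s3 = c(4, 3, 2, 1))
  cc <- pearson_matrix(m)
  expect_equal(diag(cc), c(s1 = 1, s2 = 1, s3 = 1))
  expect_equal(cc["s1", "s2"], 1, tolerance = 1e-12)   # y = 2x
  expect_equal(cc["s1", "s3"], -1, tolerance = 1e-12)  # y = -x
  expect_equal(cc, t(cc))
  expect_warning(cc2 <- pearson_matrix(rbind(m, s4 = c(5, 5, 5, 5))),
                 "constant")
  expect_true(all(is.na(cc2["s4", c("s1", "s2", "s3")])))
})
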