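norm_fixture <- function(seed = 2, n_genes = 150, n_cells = 60) {
  set.seed(seed)
  m <- named_matrix(rpois(n_genes * n_cells, 3), n_genes, n_cells)
  normalize_log(m[, colSums(m) > 0])
}

test_that("differential expression is antisymmetric and self-null", {
  norm <- norm_fixture()
  a <- colnames(norm)[1:30]; b <- colnames(norm)[31:60]
  ab <- differential_expression(norm, a, b)
  ba <- differential_expression(norm, b, a)
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  # identical groups: all fold changes zero
  aa <- differential_expression(norm, a, a)
  expect_true(all(aa$log2fc == 0))
  # detection filter empties the table with a warning
  zeros <- named_matrix(0, 10, 20); zeros[1, ] <- 1
  nz <- normalize_log(zeros)
  expect_warning(
    empty <- differential_expression(nz, colnames(nz)[1:10],
                                     colnames(nz)[11:20], min_pct = 2),
    "detection filter")
  expect_equal(nrow(empty), 0)
})

test_that("PAG thresholds are strict inequalities in both dimensions", {
  de <- data.frame(gene_id = c("a", "b", "c", "d"),
                   log2fc = c(0.30, 0.25, -0.6, 0.5),
                   p = c(0.001, 0.001, 0.01, 0.2),
                   p_adj = c(0.01, 0.01, 0.2, 0.5),
                   pct_1 = 1, pct_2 = 1)
  pags <- call_pags(de)
  expect_identical(pags$gene_id, "a")      # b at exactly 0.25 excluded
  expect_identical(pags$direction, "up")   # c/d fail the p threshold
})

test_that("reversal follows the quadrant rule in both modes", {
  pags <- call_pags(data.frame(gene_id = c("up1", "up2", "dn1"),
                               log2fc = c(0.5, 0.6, -0.7),
                               p = 0.001, p_adj = 0.01, pct_1 = 1, pct_2 = 1))
  de_regen <- data.frame(gene_id = c("up1", "up2", "dn1"),
                         log2fc = c(0.4, -0.4, -0.5),
                         p = 0.001, p_adj = c(0.01, 0.01, 0.3),
                         pct_1 = 1, pct_2 = 1)
  strict <- reversal_score(pags, de_regen, mode = "strict")
  # up1: same sign + significant -> reversed; up2: opposite quadrant;
  # dn1: same sign but not significant in the regeneration contrast
  expect_equal(strict$n_up_reversed, 1)
  expect_equal(strict$n_down_reversed, 0)
  sign_only <- reversal_score(pags, de_regen, mode = "sign_only")
  expect_equal(sign_only$n_down_reversed, 1)
  expect_equal(sign_only$pct_reversed, 100 * 2 / 3, tolerance = 1e-9)
  # a PAG missing from the regeneration contrast counts as not reversed
  expect_message(
    miss <- reversal_score(pags, de_regen[-1, ], mode = "sign_only"),
    "absent")
  expect_equal(miss$n_up_reversed, 0)
})

test_that("raising the significance threshold never loses sign-only reversals", {
  sim <- simulate_counts(tiny_design(n_genes = 300, cells = 80,
                                     conditions = 3L, reversal = 0.5, seed = 9))
  qc <- qc_filter(sim$counts, lenient_qc())
  norm <- normalize_log(qc); meta <- qc$cell_meta
  deA <- differential_expression(norm, meta$cell_id[meta$condition == "old"],
                                 meta$cell_id[meta$condition == "young"])
  deR <- differential_expression(norm, meta$cell_id[meta$condition == "old"],
                                 meta$cell_id[meta$condition == "regenerated"])
  counts <- vapply(c(0.01, 0.05, 0.2, 1), function(amax) {
    pg <- call_pags(deA, adj_p_max = amax)
    r <- reversal_score(pg, deR, mode = "sign_only")
    r$n_up_reversed + r$n_down_reversed
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("injury-response reversal counts only shared significant genes", {
  pags <- call_pags(data.frame(gene_id = c("up1", "up2", "dn1"),
                               log2fc = c(0.5, 0.6, -0.7),
                               p = 0.001, p_adj = 0.01, pct_1 = 1, pct_2 = 1))
  de6 <- data.frame(gene_id = c("up1", "dn1"),
                    log2fc = c(-0.9, -0.8),
                    p = 0.001, p_adj = 0.01, pct_1 = 1, pct_2 = 1)
  res <- injury_reversal(pags, de6)
  # up2 absent from the 6-h table: out of the denominator entirely
  expect_equal(res$n_up_shared, 1)
  expect_equal(res$pct_up_reversed, 100)    # up-PAG with negative 6-h change
  expect_equal(res$pct_down_reversed, 0)    # dn1 moves the same way at 6 h
})

test_that("a planted opposite-direction injury response is recovered", {
  # 40 PAGs; 6-h contrast built so exactly half of them flip direction
  set.seed(33)
  ids <- sprintf("g%03d", 1:40)
  dirs <- rep(c(1, -1), 20)
  pags <- call_pags(data.frame(gene_id = ids, log2fc = dirs * 0.8,
                               p = 1e-4, p_adj = 1e-3, pct_1 = 1, pct_2 = 1))
  flip <- rep(c(TRUE, FALSE), each = 20)
  de6 <- data.frame(gene_id = ids,
                    log2fc = ifelse(flip, -dirs, dirs) * 0.9,
                    p = 1e-4, p_adj = 1e-3, pct_1 = 1, pct_2 = 1)
  res <- injury_reversal(pags, de6)
  expect_equal(res$pct_reversed, 50, tolerance = 5)
})

test_that("regenerated profiles correlate with young rather than old", {
  # pseudo-bulk fixture drawn from generative means: regenerated == young
  set.seed(14)
  base <- rlnorm(400, log(50), 1)
  old <- base * 2^(sample(c(-1, 0, 1), 400, TRUE, c(0.2, 0.6, 0.2)))
  draw <- function(mu, n) vapply(seq_len(n), function(i)
    rpois(length(mu), mu), numeric(length(mu)))
  mat <- cbind(draw(base, 3), draw(old, 3), draw(base, 3))
  rownames(mat) <- sprintf("g%03d", 1:400)
  colnames(mat) <- c(paste0("y", 1:3), paste0("o", 1:3), paste0("r", 1:3))
  cond <- rep(c("young", "old", "regenerated"), each = 3)
  res <- condition_correlation(mat, cond)
  bm <- res$between_means
  get <- function(a, b) bm$mean_correlation[
    (bm$condition_1 == a & bm$condition_2 == b) |
      (bm$condition_1 == b & bm$condition_2 == a)]
  expect_gt(get("young", "regenerated"), get("old", "regenerated"))
  # duplicate sample correlates at 1; gene order is irrelevant
  expect_equal(res$correlation["y1", "y1"], 1)
  res2 <- condition_correlation(mat[sample(nrow(mat)), ], cond)
  expect_equal(res$correlation, res2$correlation, tolerance = 1e-12)
})
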