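sim_for_pb <- function(seed = 6) simulate_counts(tiny_design(
  n_genes = 200, cells = 40, conditions = 3L, seed = seed))

test_that("pseudo-bulk aggregation sums member cells exactly", {
  sim <- sim_for_pb()
  pb <- aggregate_pseudobulk(sim$counts, "sample")
  # conservation: group sums recover the full matrix total
  expect_equal(sum(pb$matrix), sum(sim$counts$matrix))
  # direct indicator-matrix oracle
  key <- sim$counts$cell_meta$sample_id
  for (s in unique(key)) {
    oracle <- Matrix::rowSums(sim$counts$matrix[, key == s, drop = FALSE])
    expect_equal(pb$matrix[, s], as.numeric(oracle), ignore_attr = TRUE)
  }
  # one cell per group reproduces that cell
  solo <- subset_cells(sim$counts, 1L)
  pb1 <- aggregate_pseudobulk(solo, "sample")
  expect_equal(as.numeric(pb1$matrix), as.numeric(solo$matrix))
  # sample x tissue groups carry the tissue covariate
  pbt <- aggregate_pseudobulk(sim$counts, "sample_tissue")
  expect_true(all(pbt$covariates$tissue == "tissue"))
})

test_that("pseudo-bulk gene filter applies inclusive thresholds", {
  m <- rbind(
    exact = c(10, 10, 0, 0, 0, 0, 0, 0, 0, 0),  # 10 UMIs in exactly 20%
    below = rep(9, 10),                          # never reaches 10
    rich  = rep(50, 10))
  colnames(m) <- paste0("s", 1:10)
  kept <- filter_and_map(m, NULL, min_umi = 10, min_fraction = 0.2)
  expect_setequal(rownames(kept), c("exact", "rich"))
  # identity map with no filtering keeps the gene set unchanged
  ident <- stats::setNames(rownames(m), rownames(m))
  same <- filter_and_map(m, ident, min_umi = 0, min_fraction = 0)
  expect_setequal(rownames(same), rownames(m))
  # mapping renames and drops unmapped genes
  map <- c(rich = "RICH")
  mapped <- filter_and_map(m, map, min_umi = 0, min_fraction = 0)
  expect_identical(rownames(mapped), "RICH")
  expect_error(filter_and_map(m, NULL, min_umi = 1000, min_fraction = 1),
               "no genes pass")
})

test_that("RLE factors equal the median-of-ratios oracle", {
  set.seed(4)
  m <- named_matrix(rpois(30 * 6, 30) + 1L, 30, 6, prefix = c("g", "s"))
  res <- rle_normalize(m)
  geo <- exp(rowMeans(log(m)))
  oracle <- apply(m / geo, 2, stats::median)
  expect_equal(res$size_factors, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # doubling one sample doubles its factor and equalizes columns
  m2 <- cbind(a = m[, 1], b = 2L * m[, 1])
  r2 <- rle_normalize(m2)
  expect_equal(unname(r2$size_factors["b"] / r2$size_factors["a"]), 2)
  expect_equal(r2$matrix[, "a"], r2$matrix[, "b"], tolerance = 1e-12)
  all_zero_somewhere <- named_matrix(c(0L, 1L, 1L, 0L), 2, 2)
  expect_error(rle_normalize(all_zero_somewhere), "reference genes")
})

test_that("age model recovers planted slopes and the score convention", {
  ages <- c(5, 5, 5, 5, 7, 7, 12, 12, 18, 18, 32, 32)
  slopes <- vapply(1:40, function(s) {
    set.seed(s)
    y <- 500 * ages * exp(rnorm(12, 0, 0.1))
    age_model(matrix(y, 1, 12, dimnames = list("g", NULL)), ages)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1), 0.15)
  # constant gene: slope 0, score 0
  flat <- age_model(matrix(100, 1, 12, dimnames = list("g", NULL)), ages)
  expect_equal(flat$slope, 0)
  expect_equal(flat$rank_score, 0)
  # score is -log10(p) carrying the slope sign
  am <- data.frame(pv = c(0.01, 0.01), slope = c(2, -3))
  s <- ifelse(am$slope == 0, 0, -log10(am$pv) * sign(am$slope))
  expect_equal(s, c(2, -2))
  expect_error(age_model(matrix(1:6, 2, 3), c(5, 5, 5)), "no age contrast")
})

test_that("enrichment scores match fgsea and respect antisymmetry", {
  set.seed(3)
  scores <- stats::setNames(rnorm(500), sprintf("r%04d", 1:500))
  sets <- simulate_genesets(500, 5, set_size = 25, planted_top = 40, seed = 9)
  res <- preranked_gsea(scores, sets, n_perm = 200, seed = 4)
  expect_true(all(res$es >= -1 & res$es <= 1))
  expect_true(all(sign(res$nes) == sign(res$es)))
  expect_true(all(res$p_adj >= res$p - 1e-12))
  fg <- suppressWarnings(fgsea::fgsea(
    pathways = sets, stats = sort(scores, decreasing = TRUE),
    nperm = 200, gseaParam = 1))
  cmp <- merge(res[, c("set", "es")], as.data.frame(fg)[, c("pathway", "ES")],
               by.x = "set", by.y = "pathway")
  expect_equal(cmp$es, cmp$ES, tolerance = 1e-10)
  # negating every score flips every enrichment sign
  res_neg <- preranked_gsea(-scores, sets, n_perm = 200, seed = 4)
  ord <- order(res$set); ordn <- order(res_neg$set)
  expect_equal(res$es[ord], -res_neg$es[ordn], tolerance = 1e-10)
  # determinism
  expect_identical(res, preranked_gsea(scores, sets, n_perm = 200, seed = 4))
  # undersized sets are skipped
  expect_warning(
    preranked_gsea(scores, list(tiny = c("r0001", "zzz", "yyy")),
                   n_perm = 50, seed = 1),
    "skipping")
})

test_that("a set planted at the top of the ranking is maximally enriched", {
  sc <- stats::setNames(sort(rnorm(800, 0, 2), decreasing = TRUE),
                        sprintf("g%04d", 1:800))
  res <- preranked_gsea(sc, list(top = names(sc)[1:20]),
                        n_perm = 1000, seed = 3)
  expect_gt(res$es, 0)
  expect_gt(res$nes, 0)
  expect_equal(res$p, 1 / 1001, tolerance = 1e-12)
})

test_that("signature PCA separates opposed signatures and is degenerate-safe", {
  set.seed(12)
  base <- rnorm(100)
  m <- cbind(sigA = base, sigB = base, sigC = -base + rnorm(100, 0, 0.01))
  rownames(m) <- sprintf("g%03d", 1:100)
  pc <- signature_pca(m)
  # identical signatures land on identical coordinates
  expect_equal(pc$coordinates["sigA", ], pc$coordinates["sigB", ],
               tolerance = 1e-8)
  # the negated signature sits far from both on PC1
  d_ab <- abs(pc$coordinates["sigA", 1] - pc$coordinates["sigB", 1])
  d_ac <- abs(pc$coordinates["sigA", 1] - pc$coordinates["sigC", 1])
  expect_gt(d_ac, 10 * d_ab + 1)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-9)
  expect_error(signature_pca(m[0, ]), "fewer than 2 genes")
  expect_error(signature_pca(m[, 1, drop = FALSE]), ">= 2 signatures")
})

test_that("young-derived signatures cluster apart from old-derived ones", {
  # three signed-score signatures: two from young-like age models, one from
  # an old-like model with inverted associations on a gene subset
  wins <- vapply(1:20, function(s) {
    set.seed(s)
    core <- rnorm(300)
    youngA <- core + rnorm(300, 0, 0.3)
    youngB <- core + rnorm(300, 0, 0.3)
    oldC <- -core + rnorm(300, 0, 0.3)
    m <- cbind(youngA, youngB, oldC)
    rownames(m) <- sprintf("g%03d", 1:300)
    pc <- signature_pca(m)$coordinates
    dist(pc[c("youngA", "youngB"), ])[1] < dist(pc[c("youngA", "oldC"), ])[1]
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})
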