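test_that("composition fractions sum to one and tests follow group count", {
  sim <- simulate_counts(tiny_design(n_genes = 200, cells = 40, conditions = 3L,
                                     seed = 3))
  d <- sim$counts
  d$cell_meta$tissue <- rep_len(c("tA", "tB"), nrow(d$cell_meta))
  comp <- composition(d)
  sums <- tapply(comp$table$fraction, comp$table$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(comp$tests$method == "anova_tukey"))  # three conditions
  # two conditions use Welch
  two <- d
  keep <- two$cell_meta$condition != "regenerated"
  two <- subset_cells(two, which(keep))
  expect_true(all(grepl("welch", composition(two)$tests$method)))
  # a single condition yields the table only
  one <- subset_cells(d, which(d$cell_meta$condition == "young"))
  expect_null(composition(one)$tests)
})

test_that("a planted proportion shift is recovered in the composition table", {
  samples <- data.frame(
    sample_id = c(paste0("y", 1:3), paste0("o", 1:3)),
    condition = rep(c("young", "old"), each = 3),
    age_months = rep(c(6, 24), each = 3))
  d <- simulation_design(
    n_genes = 150, cell_types = c("neuron", "other"), samples = samples,
    cells_per_sample_per_type = 100,
    pag_spec = list(neuron = list(n_up = 0, n_down = 0, effect_log2fc = 0)),
    proportion_shift = list(old = c(neuron = 0.5)),
    doublet_fraction = 0, seed = 5)
  sim <- simulate_counts(d)
  comp <- composition(sim$counts)
  tab <- comp$table[comp$table$tissue == "neuron", ]
  expect_lt(mean(tab$fraction[tab$condition == "old"]),
            mean(tab$fraction[tab$condition == "young"]))
  expect_equal(mean(tab$fraction[tab$condition == "young"]), 0.5,
               tolerance = 0.02)
})

test_that("marker-positive fractions count detection above threshold", {
  m <- named_matrix(0, 10, 50)
  m["g0001", 1:5] <- 2          # 10% positive in sample s1
  samples <- rep("s1", 50)
  res <- marker_positive_fraction(m, samples, "g0001")
  expect_equal(res$fraction_positive, 0.1)
  # threshold below the minimum expressed value equals the detection fraction
  res2 <- marker_positive_fraction(m, samples, "g0001", threshold = 1)
  expect_equal(res2$fraction_positive, 0.1)
  res3 <- marker_positive_fraction(m, samples, "g0002")
  expect_equal(res3$fraction_positive, 0)
  expect_error(marker_positive_fraction(m, samples, "absent"), "absent")
})

test_that("a planted marker-positive population is recovered within 2 pp", {
  set.seed(21)
  n <- 1000
  m <- named_matrix(rpois(50 * n, 0.2), 50, n)
  pos <- sample(n, 100)                       # 10% planted positive
  m["g0001", ] <- 0
  m["g0001", pos] <- rpois(100, 8) + 1L
  norm <- normalize_log(m[, colSums(m) > 0])
  res <- marker_positive_fraction(norm, rep("s", ncol(norm)), "g0001")
  expect_lt(abs(res$fraction_positive - 0.10), 0.02)
})

test_that("cell-cycle scoring is centered, seeded, and order-invariant", {
  set.seed(8)
  norm <- named_matrix(abs(rnorm(500 * 80, 1, 0.2)), 500, 80)
  s_genes <- rownames(norm)[1:15]
  g2m_genes <- rownames(norm)[16:30]
  a <- cell_cycle_score(norm, s_genes, g2m_genes, seed = 4)
  b <- cell_cycle_score(norm, s_genes, g2m_genes, seed = 4)
  expect_identical(a, b)
  # scrambling gene order leaves scores unchanged
  perm <- sample(nrow(norm))
  c_ <- cell_cycle_score(norm[perm, ], s_genes, g2m_genes, seed = 4)
  expect_equal(a$s_score, c_$s_score, tolerance = 1e-12)
  # a zero-signal matrix scores zero and assigns G1 everywhere
  flat <- named_matrix(1, 100, 30)
  z <- cell_cycle_score(flat, rownames(flat)[1:10], rownames(flat)[11:20],
                        seed = 1)
  expect_true(all(abs(z$s_score) < 1e-12))
  expect_true(all(z$phase == "G1"))
  expect_error(cell_cycle_score(norm, "nope", g2m_genes), "S-panel")
})

test_that("planted cell-cycle programs are recovered with high accuracy", {
  d <- tiny_design(n_genes = 600, cells = 250, seed = 5)
  sim <- simulate_counts(d)
  qc <- qc_filter(sim$counts, lenient_qc())
  norm <- normalize_log(qc)
  cc <- cell_cycle_score(norm, sim$truth$s_genes, sim$truth$g2m_genes, seed = 3)
  truth <- unlist(sim$truth$true_phase)[cc$cell_id]
  cycling <- truth %in% c("S", "G2M")
  expect_gte(mean(cc$phase[cycling] == truth[cycling]), 0.95)
})

test_that("G1 fractions aggregate per group", {
  calls <- data.frame(cell_id = paste0("c", 1:6),
                      s_score = 0, g2m_score = 0,
                      phase = c("G1", "G1", "S", "G1", "G2M", "G1"))
  res <- g1_fraction_by_group(calls, c("a", "a", "a", "b", "b", "b"))
  expect_equal(res$g1_fraction, c(2 / 3, 2 / 3))
  all_g1 <- calls; all_g1$phase <- "G1"
  expect_true(all(g1_fraction_by_group(all_g1, rep("x", 6))$g1_fraction == 1))
})
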