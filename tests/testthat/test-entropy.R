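test_that("vector length, distance and angle match their definitions", {
  expect_equal(vector_length(c(3, 4)), 5)
  expect_equal(vector_length(rep(0, 10)), 0)
  set.seed(2)
  v <- rnorm(2000)
  oracle <- sqrt(sum(vapply(v, function(x) x^2, numeric(1))))
  expect_equal(vector_length(v), oracle, tolerance = 1e-12)

  expect_equal(mutual_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(mutual_distance(c(1, 0), c(0, 1)), sqrt(2))
  u <- rnorm(500); w <- rnorm(500)
  d_oracle <- sqrt(sum((u - w)^2))
  expect_equal(mutual_distance(u, w), d_oracle, tolerance = 1e-12)
  expect_error(mutual_distance(1:3, 1:4), "panel")

  expect_equal(mutual_angle(c(2, 1), c(2, 1)), 0)
  expect_equal(mutual_angle(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(mutual_angle(c(1, 1), c(1, 0)), pi / 4)
  expect_error(mutual_angle(c(0, 0), c(1, 0)), "zero vector")
})

test_that("group summaries equal an explicit double-loop oracle", {
  set.seed(7)
  X <- named_matrix(abs(rnorm(40 * 8)), 8, 40)
  groups <- rep(c("a", "b"), each = 20)
  res <- group_entropy(X, groups)
  for (g in c("a", "b")) {
    cells <- which(groups == g)
    ds <- c(); as_ <- c(); ls <- c()
    for (i in cells) ls <- c(ls, vector_length(X[, i]))
    for (i in seq_along(cells)) for (j in seq_along(cells)) if (i < j) {
      ds <- c(ds, mutual_distance(X[, cells[i]], X[, cells[j]]))
      as_ <- c(as_, mutual_angle(X[, cells[i]], X[, cells[j]]))
    }
    row <- res[res$group == g, ]
    expect_equal(row$mean_length, mean(ls), tolerance = 1e-10)
    expect_equal(row$mean_mutual_distance, mean(ds), tolerance = 1e-10)
    expect_equal(row$mean_mutual_angle, mean(as_), tolerance = 1e-10)
    expect_equal(row$n_pairs_used, choose(20, 2))
  }
})

test_that("degenerate groups are handled as documented", {
  X <- matrix(rep(c(1, 2, 3), 3), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  res <- group_entropy(X, rep("same", 3))
  expect_equal(res$mean_mutual_distance, 0)
  expect_equal(res$mean_mutual_angle, 0)
  single <- group_entropy(X[, 1, drop = FALSE], "solo")
  expect_true(is.na(single$mean_mutual_distance))
  expect_true(is.na(single$mean_mutual_angle))
  expect_equal(single$mean_length, vector_length(X[, 1]))
  expect_equal(single$n_pairs_used, 0L)
})

test_that("pair subsampling is seeded, recorded, and unbiased", {
  X <- simulate_gaussian_cells(rep(0, 20), diag(20), 300, seed = 5)
  full <- group_entropy(X, rep("g", 300))
  sub <- group_entropy(X, rep("g", 300), max_pairs = 5000L, seed = 9)
  sub2 <- group_entropy(X, rep("g", 300), max_pairs = 5000L, seed = 9)
  expect_identical(sub, sub2)
  expect_equal(sub$n_pairs_used, 5000L)
  expect_false(is.na(sub$subsample_seed))
  expect_lt(abs(sub$mean_mutual_distance - full$mean_mutual_distance) /
              full$mean_mutual_distance, 0.02)
})

test_that("Gaussian entropy matches numerical integration and scaling laws", {
  h1 <- gaussian_entropy(matrix(1))
  num <- stats::integrate(function(x) {
    p <- stats::dnorm(x); ifelse(p > 0, -p * log(p), 0)
  }, -Inf, Inf)$value
  expect_equal(h1, num, tolerance = 1e-8)
  expect_equal(h1, 0.5 * (1 + log(2 * pi)), tolerance = 1e-12)
  # scaling: H(c * Sigma) = H(Sigma) + D/2 * log(c)
  sig <- crossprod(matrix(rnorm(16), 4))
  diag(sig) <- diag(sig) + 0.5
  expect_equal(gaussian_entropy(3 * sig), gaussian_entropy(sig) + 2 * log(3),
               tolerance = 1e-10)
  # diagonal decomposition
  expect_equal(gaussian_entropy(diag(c(1, 4))),
               gaussian_entropy(diag(2)) + 0.5 * log(4), tolerance = 1e-12)
  expect_error(gaussian_entropy(matrix(c(1, 1, 1, 1), 2)), "singular")
})

test_that("expected mutual distance is the RMS closed form and a tight bound", {
  expect_equal(expected_mutual_distance(diag(10)), sqrt(20))
  expect_equal(expected_mutual_distance(matrix(0, 3, 3)), 0)
  # the Monte-Carlo mean distance sits just below sqrt(2 Tr Sigma)
  X <- simulate_gaussian_cells(rep(0, 100), diag(100), 1500, seed = 12)
  emp <- group_entropy(X, rep("g", 1500), max_pairs = 200000L,
                       seed = 1)$mean_mutual_distance
  bound <- expected_mutual_distance(diag(100))
  expect_lte(emp, bound)
  expect_lt((bound - emp) / bound, 0.003)
})

test_that("mean mutual distance increases with covariance scale", {
  # Sigma vs 4 Sigma: the larger covariance wins in every seeded replicate
  wins <- vapply(1:30, function(s) {
    A <- simulate_gaussian_cells(rep(0, 10), diag(10), 40, seed = s)
    B <- simulate_gaussian_cells(rep(0, 10), 4 * diag(10), 40, seed = 1000 + s)
    ga <- group_entropy(A, rep("a", 40))$mean_mutual_distance
    gb <- group_entropy(B, rep("b", 40))$mean_mutual_distance
    gb > ga
  }, logical(1))
  expect_true(all(wins))
})

test_that("mean mutual angle is invariant to positive per-cell rescaling", {
  set.seed(30)
  X <- named_matrix(abs(rnorm(20 * 6)) + 0.1, 6, 20)
  scales <- runif(20, 0.5, 5)
  Xs <- sweep(X, 2, scales, "*")
  a1 <- group_entropy(X, rep("g", 20))$mean_mutual_angle
  a2 <- group_entropy(Xs, rep("g", 20))$mean_mutual_angle
  expect_equal(a1, a2, tolerance = 1e-10)
})
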