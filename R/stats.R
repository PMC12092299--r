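#' Construct a test-result record
#'
#' Uniform container used by every statistical kernel in the package.
#'
#' @param statistic test statistic.
#' @param p two-sided p-value in `[0, 1]`.
#' @param method short method tag (e.g. `"wilcoxon_exact"`, `"fisher"`).
#' @param df degrees of freedom, if meaningful.
#' @param n sample sizes.
#' @param degenerate `TRUE` when the inputs admit no real test (e.g. all
#'   values tied) and the result is the conventional fallback.
#' @return a `test_result` list.
#' @keywords internal
test_result <- function(statistic, p, method, df = NULL, n = NULL,
                        degenerate = FALSE) {
  stopifnot(p >= 0, p <= 1 + 1e-12)
  structure(list(statistic = unname(statistic), p = min(unname(p), 1),
                 method = method, df = df, n = n, degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, p = %.4g%s\n",
              x$method, x$statistic, x$p,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact mode enumerates the full permutation distribution of the rank sum
#' (all `choose(nx+ny, nx)` group assignments; ties handled naturally since
#' pooled ranks are permuted), and reports the two-sided permutation
#' p-value `P(|W - E(W)| >= |w_obs - E(W)|)`. Normal mode uses the
#' tie-corrected normal approximation with continuity correction. The
#' default `"auto"` uses exact enumeration when `nx + ny <= 12` and the
#' approximation otherwise.
#'
#' @param x,y numeric samples, both non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return a `test_result`; statistic is the Mann-Whitney U of `x`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact")$p  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  assert_that(length(x) > 0 && length(y) > 0, "both samples must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(test_result(nx * ny / 2, 1, "wilcoxon_degenerate",
                       n = c(nx, ny), degenerate = TRUE))
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])          # rank sum of x
  u_obs <- w_obs - nx * (nx + 1) / 2    # Mann-Whitney U
  if (mode == "auto") mode <- if (N <= 12) "exact" else "normal"

  if (mode == "exact") {
    assert_that(N <= 20, "exact enumeration limited to combined n <= 20")
    combs <- utils::combn(N, nx)
    w_all <- colSums(matrix(r[combs], nrow = nx))
    mu <- mean(w_all)
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    return(test_result(u_obs, p, "wilcoxon_exact", n = c(nx, ny)))
  }

  # tie-corrected normal approximation with continuity correction
  ties <- table(r)
  sigma2 <- (nx * ny / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0)
    return(test_result(u_obs, 1, "wilcoxon_degenerate",
                       n = c(nx, ny), degenerate = TRUE))
  mu_u <- nx * ny / 2
  z <- (u_obs - mu_u - sign(u_obs - mu_u) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result(u_obs, p, "wilcoxon_normal", n = c(nx, ny))
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = outcome present/absent).
#' @param correction apply the Yates continuity correction (default off).
#' @return a `test_result` with `df = 1`. A zero row or column margin is
#'   degenerate: statistic 0, p 1.
#' @examples
#' chi2_2x2(matrix(c(14, 0, 77, 217), nrow = 2))$p  # < 0.001
#' @export
chi2_2x2 <- function(tab, correction = FALSE) {
  tab <- as.matrix(tab)
  assert_that(all(dim(tab) == c(2L, 2L)), "table must be 2x2")
  assert_that(all(tab >= 0), "counts must be non-negative")
  assert_that(sum(tab) > 0, "grand total must be positive")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(test_result(0, 1, "chi2_degenerate", df = 1, degenerate = TRUE))
  res <- suppressWarnings(stats::chisq.test(tab, correct = correction))
  test_result(res$statistic, res$p.value,
              if (correction) "chi2_yates" else "chi2", df = 1)
}

#' Gene-set enrichment 2x2 test with chi-squared/Fisher switching
#'
#' Builds the 2x2 table (in set vs background-outside-set, hit vs not) and
#' applies the Pearson chi-squared test when all four expected frequencies
#' exceed 5, otherwise Fisher's exact test (two-sided by summing all tables
#' with fixed margins whose probability does not exceed the observed
#' table's). The method tag records which branch ran.
#'
#' @param in_set_hits,in_set_total hits and size of the query set.
#' @param background_hits,background_total hits and size of the background
#'   universe (which contains the set).
#' @return a `test_result` tagged `"chi2"` or `"fisher"`.
#' @export
enrichment_test <- function(in_set_hits, in_set_total,
                            background_hits, background_total) {
  assert_that(in_set_hits <= in_set_total, "hits cannot exceed set size")
  assert_that(background_hits <= background_total,
              "background hits cannot exceed background size")
  assert_that(background_total >= in_set_total,
              "background must contain the set")
  assert_that(background_hits >= in_set_hits,
              "background hits must include set hits")
  out_hits <- background_hits - in_set_hits
  out_total <- background_total - in_set_total
  tab <- matrix(c(in_set_hits, in_set_total - in_set_hits,
                  out_hits, out_total - out_hits),
                nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected > 5)) {
    res <- chi2_2x2(tab, correction = FALSE)
    res$method <- "chi2"
    res
  } else {
    p <- stats::fisher.test(tab)$p.value
    test_result(NA_real_, p, "fisher")
  }
}

#' Two-sided Welch's t-test
#'
#' @param x,y numeric samples with at least two observations each.
#' @return a `test_result` with Welch-Satterthwaite degrees of freedom.
#'   Zero variance in both groups is degenerate: p 1 if means are equal,
#'   p 0 otherwise.
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  assert_that(length(x) >= 2 && length(y) >= 2,
              "each group needs >= 2 observations")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(test_result(if (same) 0 else Inf, if (same) 1 else 0,
                       "welch_degenerate", n = c(length(x), length(y)),
                       degenerate = TRUE))
  }
  res <- stats::t.test(x, y, var.equal = FALSE)
  test_result(res$statistic, res$p.value, "welch_t",
              df = unname(res$parameter), n = c(length(x), length(y)))
}

#' One-way ANOVA with Tukey's HSD post hoc comparisons
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @return list with `anova_p`, `statistic` (F) and `pairs`, a data.frame of
#'   pairwise mean differences with Tukey-adjusted p-values from the
#'   studentized-range distribution. All-constant input is degenerate
#'   (p = 1 everywhere).
#' @export
anova_tukey <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2, "need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (all(vapply(groups, function(g) stats::var(g) %in% c(0, NA), logical(1))) &&
      length(unique(value)) <= length(groups) &&
      stats::var(vapply(groups, mean, numeric(1))) == 0) {
    combos <- utils::combn(names(groups), 2)
    pairs <- data.frame(comparison = paste(combos[2, ], combos[1, ], sep = "-"),
                        diff = 0, p_adj = 1)
    return(list(anova_p = 1, statistic = 0, pairs = pairs, degenerate = TRUE))
  }
  fit <- stats::aov(value ~ grp)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$grp
  pairs <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(anova_p = an[["Pr(>F)"]][1], statistic = an[["F value"]][1],
       pairs = pairs, degenerate = FALSE)
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up with enforced
#' monotonicity; the adjusted values map back to the input order.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_p <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Sample-by-sample Pearson correlation matrix
#'
#' @param mat numeric samples x genes matrix.
#' @return symmetric samples x samples correlation matrix with unit
#'   diagonal; constant samples produce `NA` rows/columns (diagonal kept 1)
#'   with a warning.
#' @export
pearson_matrix <- function(mat) {
  mat <- as.matrix(mat)
  assert_that(ncol(mat) >= 2, "need >= 2 genes")
  constant <- apply(mat, 1, function(r) stats::sd(r) == 0)
  if (any(constant))
    warning("constant sample(s): ",
            paste(rownames(mat)[constant], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  cc <- suppressWarnings(stats::cor(t(mat)))
  diag(cc) <- 1
  cc
}
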