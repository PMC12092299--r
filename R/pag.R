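#' Wilcoxon differential expression between two cell groups
#'
#' For every gene detected in at least `min_pct` of either group, computes
#' a log2 fold change on de-logged group means,
#' `log2(mean(expm1(x_A)) + pc) - log2(mean(expm1(x_B)) + pc)`, and a
#' two-sided Wilcoxon rank-sum p-value on the normalized values
#' (tie-corrected normal approximation), Bonferroni-adjusted over the
#' tested genes. The first-named group is the numerator, so swapping the
#' groups negates every log2FC and leaves p-values unchanged.
#'
#' @param norm gene x cell matrix of normalized log expression.
#' @param cells_a,cells_b cell ids (or column indices) of the two groups,
#'   each with >= 3 cells.
#' @param min_pct minimal detection fraction in either group for a gene to
#'   be tested.
#' @param pseudocount added to de-logged group means before log2.
#' @return data.frame: `gene_id`, `log2fc`, `p`, `p_adj`, `pct_1`, `pct_2`.
#' @export
differential_expression <- function(norm, cells_a, cells_b,
                                    min_pct = 0.1, pseudocount = 1) {
  A <- norm[, cells_a, drop = FALSE]
  B <- norm[, cells_b, drop = FALSE]
  assert_that(ncol(A) >= 3 && ncol(B) >= 3,
              "both groups need >= 3 cells")
  pct1 <- Matrix::rowMeans(A > 0)
  pct2 <- Matrix::rowMeans(B > 0)
  tested <- which(pct1 >= min_pct | pct2 >= min_pct)
  if (!length(tested)) {
    warning("no genes pass the detection filter", call. = FALSE)
    return(data.frame(gene_id = character(), log2fc = numeric(),
                      p = numeric(), p_adj = numeric(),
                      pct_1 = numeric(), pct_2 = numeric()))
  }
  expm1_mean <- function(m) {
    e <- m
    if (methods::is(e, "sparseMatrix")) { e@x <- expm1(e@x); Matrix::rowMeans(e) }
    else rowMeans(expm1(e))
  }
  mean_a <- expm1_mean(A[tested, , drop = FALSE])
  mean_b <- expm1_mean(B[tested, , drop = FALSE])
  lfc <- log2(mean_a + pseudocount) - log2(mean_b + pseudocount)

  Xa <- as.matrix(A[tested, , drop = FALSE])
  Xb <- as.matrix(B[tested, , drop = FALSE])
  na <- ncol(Xa); nb <- ncol(Xb); N <- na + nb
  p <- vapply(seq_along(tested), function(i) {
    pooled <- c(Xa[i, ], Xb[i, ])
    if (length(unique(pooled)) == 1L) return(1)
    r <- rank(pooled)
    u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    ties <- table(r)
    s2 <- (na * nb / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (s2 <= 0) return(1)
    z <- (u - na * nb / 2 - sign(u - na * nb / 2) * 0.5) / sqrt(s2)
    min(1, 2 * stats::pnorm(-abs(z)))
  }, numeric(1))

  data.frame(gene_id = rownames(norm)[tested], log2fc = unname(lfc),
             p = p, p_adj = adjust_p(p, "bonferroni"),
             pct_1 = unname(pct1[tested]), pct_2 = unname(pct2[tested]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call age-associated genes from an old-vs-young contrast
#'
#' A gene qualifies when `|log2FC| > log2fc_min` (strict) and
#' `p_adj < adj_p_max` (strict); the sign of the old-vs-young log2FC sets
#' the direction.
#'
#' @param de old-vs-young [differential_expression()] table (old as the
#'   first group).
#' @param log2fc_min,adj_p_max calling thresholds (defaults 0.25, 0.05).
#' @param tissue optional tissue label carried through.
#' @return a `pag_table`: the qualifying DE rows plus a `direction`
#'   column (`"up"`/`"down"`), with the tissue in attribute `"tissue"`.
#' @export
call_pags <- function(de, log2fc_min = 0.25, adj_p_max = 0.05,
                      tissue = NA_character_) {
  keep <- abs(de$log2fc) > log2fc_min & de$p_adj < adj_p_max
  out <- de[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  structure(out, class = c("pag_table", "data.frame"), tissue = tissue)
}

#' Rejuvenation-reversal scoring of age-associated genes
#'
#' A PAG counts as reversed when its old-vs-regenerated log2FC has the same
#' sign as its old-vs-young log2FC (old is the extreme condition in both
#' contrasts, i.e. regeneration restored youthful expression). In the
#' default `"strict"` mode the regeneration contrast must additionally be
#' significant (`|log2FC| > log2fc_min`, `p_adj < adj_p_max`);
#' `"sign_only"` drops that requirement. PAGs absent from the regeneration
#' contrast count as not reversed.
#'
#' @param pags a [call_pags()] table.
#' @param de_regen old-vs-regenerated [differential_expression()] table
#'   (old as the first group).
#' @param log2fc_min,adj_p_max strict-mode thresholds.
#' @param mode `"strict"` or `"sign_only"`.
#' @return list: `n_up`, `n_down`, `n_up_reversed`, `n_down_reversed`,
#'   `pct_up_reversed`, `pct_down_reversed`, `pct_reversed` (pooled),
#'   `reversed_ids`, `tissue`, `mode`.
#' @export
reversal_score <- function(pags, de_regen, log2fc_min = 0.25,
                           adj_p_max = 0.05,
                           mode = c("strict", "sign_only")) {
  mode <- match.arg(mode)
  idx <- match(pags$gene_id, de_regen$gene_id)
  missing <- sum(is.na(idx))
  if (missing > 0)
    message(missing, " PAG(s) absent from the regeneration contrast; ",
            "counted as not reversed")
  lfc_r <- de_regen$log2fc[idx]
  padj_r <- de_regen$p_adj[idx]
  same_sign <- !is.na(lfc_r) & sign(lfc_r) == sign(pags$log2fc) & lfc_r != 0
  reversed <- if (mode == "strict")
    same_sign & abs(lfc_r) > log2fc_min & padj_r < adj_p_max
  else same_sign
  reversed[is.na(reversed)] <- FALSE

  up <- pags$direction == "up"
  n_up <- sum(up); n_down <- sum(!up)
  n_up_rev <- sum(reversed & up); n_down_rev <- sum(reversed & !up)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(n_up = n_up, n_down = n_down,
       n_up_reversed = n_up_rev, n_down_reversed = n_down_rev,
       pct_up_reversed = pct(n_up_rev, n_up),
       pct_down_reversed = pct(n_down_rev, n_down),
       pct_reversed = pct(n_up_rev + n_down_rev, n_up + n_down),
       reversed_ids = pags$gene_id[reversed],
       tissue = attr(pags, "tissue"), mode = mode)
}

#' Reversal of age-associated genes by the early injury response
#'
#' Among PAGs that are also significant in a 6h-vs-0h injury contrast
#' (shared genes), the fraction whose injury-response direction is opposite
#' to their aging direction, reported separately for up- and
#' down-regulated PAGs and pooled. PAGs absent from the injury table are
#' excluded from the denominator.
#'
#' @param pags a [call_pags()] table.
#' @param de_6h 6h-vs-0h [differential_expression()] table.
#' @param log2fc_min,adj_p_max significance thresholds for "shared".
#' @return list: `n_up_shared`, `n_down_shared`, per-direction and pooled
#'   reversed fractions (in percent; `NA` when no genes are shared).
#' @export
injury_reversal <- function(pags, de_6h, log2fc_min = 0.25,
                            adj_p_max = 0.05) {
  idx <- match(pags$gene_id, de_6h$gene_id)
  lfc6 <- de_6h$log2fc[idx]
  padj6 <- de_6h$p_adj[idx]
  shared <- !is.na(lfc6) & abs(lfc6) > log2fc_min & padj6 < adj_p_max
  if (!any(shared))
    message("no PAGs shared with the injury contrast")
  opposite <- shared & sign(lfc6) == -sign(pags$log2fc)
  up <- pags$direction == "up"
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(n_up_shared = sum(shared & up), n_down_shared = sum(shared & !up),
       pct_up_reversed = pct(sum(opposite & up), sum(shared & up)),
       pct_down_reversed = pct(sum(opposite & !up), sum(shared & !up)),
       pct_reversed = pct(sum(opposite), sum(shared)))
}

#' Condition-level Pearson correlation of (pseudo-)bulk profiles
#'
#' Correlates log-transformed expression profiles between samples and
#' summarizes the mean correlation between each pair of conditions
#' (whether regenerated samples correlate better with young than with old
#' ones is the question this answers).
#'
#' @param mat gene x sample non-negative expression matrix.
#' @param conditions condition label per sample (column).
#' @param log apply `log1p` before correlating (default `TRUE`).
#' @return list: `correlation` (sample x sample matrix) and
#'   `between_means` data.frame (`condition_1`, `condition_2`,
#'   `mean_correlation`, excluding self-pairs within a condition pair).
#' @export
condition_correlation <- function(mat, conditions, log = TRUE) {
  mat <- as.matrix(mat)
  assert_that(length(conditions) == ncol(mat),
              "one condition label per sample is required")
  x <- if (log) log1p(mat) else mat
  cc <- pearson_matrix(t(x))
  lv <- unique(conditions)
  combos <- expand.grid(i = seq_along(lv), j = seq_along(lv))
  combos <- combos[combos$i <= combos$j, ]
  between <- do.call(rbind, lapply(seq_len(nrow(combos)), function(k) {
    ci <- lv[combos$i[k]]; cj <- lv[combos$j[k]]
    block <- cc[conditions == ci, conditions == cj, drop = FALSE]
    vals <- if (ci == cj) block[lower.tri(block)] else as.numeric(block)
    data.frame(condition_1 = ci, condition_2 = cj,
               mean_correlation = mean(vals), stringsAsFactors = FALSE)
  }))
  list(correlation = cc, between_means = between)
}
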