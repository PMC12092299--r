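#' Aggregate single cells into pseudo-bulk profiles
#'
#' Sums UMI counts over all member cells per group — per sample (all
#' tissues) or per sample x tissue — to obtain bulk-like profiles that are
#' robust to dropout. Sample covariates (age, condition, tissue scope) are
#' carried over.
#'
#' @param counts an [annotated_counts()].
#' @param group_by `"sample"` or `"sample_tissue"`.
#' @return a `pseudo_bulk` list: `matrix` (gene x group summed counts) and
#'   `covariates` (group, sample_id, age_months, condition, tissue).
#' @export
aggregate_pseudobulk <- function(counts, group_by = c("sample", "sample_tissue")) {
  stopifnot(inherits(counts, "annotated_counts"))
  group_by <- match.arg(group_by)
  meta <- counts$cell_meta
  key <- if (group_by == "sample") meta$sample_id
         else paste(meta$sample_id, meta$tissue, sep = "|")
  f <- factor(key)
  ind <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                              dims = c(length(f), nlevels(f)))
  pb <- as.matrix(counts$matrix %*% ind)
  colnames(pb) <- levels(f)
  rownames(pb) <- counts$gene_ids
  first <- match(levels(f), key)
  cov <- data.frame(
    group = levels(f),
    sample_id = meta$sample_id[first],
    age_months = if ("age_months" %in% names(meta)) meta$age_months[first] else NA,
    condition = meta$condition[first],
    tissue = if (group_by == "sample_tissue") meta$tissue[first] else "all",
    stringsAsFactors = FALSE)
  structure(list(matrix = pb, covariates = cov), class = "pseudo_bulk")
}

#' Filter pseudo-bulk genes and map identifiers through an ortholog table
#'
#' Genes are renamed through a one-to-one map (unmapped genes dropped),
#' then kept only if they reach `min_umi` counts (inclusive) in at least
#' `ceiling(min_fraction * n_samples)` samples (inclusive).
#'
#' @param pb a `pseudo_bulk` from [aggregate_pseudobulk()] (or a plain
#'   gene x sample matrix).
#' @param map named character vector (`map[old_id] == new_id`), e.g. from
#'   [read_ortholog_map()]; `NULL` keeps identifiers unchanged.
#' @param min_umi,min_fraction detection thresholds (defaults 10, 0.2).
#' @return same type as `pb`, restricted and renamed.
#' @export
filter_and_map <- function(pb, map = NULL, min_umi = 10, min_fraction = 0.2) {
  is_pb <- inherits(pb, "pseudo_bulk")
  m <- if (is_pb) pb$matrix else as.matrix(pb)
  if (!is.null(map)) {
    keep <- rownames(m) %in% names(map)
    m <- m[keep, , drop = FALSE]
    rownames(m) <- unname(map[rownames(m)])
  }
  need <- ceiling(min_fraction * ncol(m))
  keep <- rowSums(m >= min_umi) >= need
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0)
    stop("no genes pass the pseudo-bulk detection filter", call. = FALSE)
  if (is_pb) structure(list(matrix = m, covariates = pb$covariates),
                       class = "pseudo_bulk") else m
}

#' Relative-log-expression (median-of-ratios) normalization
#'
#' Size factor of a sample: the median, over reference genes (genes with
#' nonzero counts in every sample), of that sample's count divided by the
#' gene's geometric mean across samples. Every gene is then divided by the
#' factors, including genes excluded from factor estimation.
#'
#' @param pb a `pseudo_bulk` or gene x sample matrix.
#' @return list: `matrix` (normalized), `size_factors` (per sample),
#'   `covariates` when present.
#' @export
rle_normalize <- function(pb) {
  is_pb <- inherits(pb, "pseudo_bulk")
  m <- if (is_pb) pb$matrix else as.matrix(pb)
  ref <- rowSums(m == 0) == 0
  if (!any(ref))
    stop("no reference genes (every gene has a zero count in some sample)",
         call. = FALSE)
  geo <- exp(rowMeans(log(m[ref, , drop = FALSE])))
  sf <- apply(m[ref, , drop = FALSE] / geo, 2, stats::median)
  norm <- sweep(m, 2, sf, "/")
  out <- list(matrix = norm, size_factors = sf)
  if (is_pb) out$covariates <- pb$covariates
  out
}

#' Per-gene log-log age model and signed ranking score
#'
#' For every gene, ordinary least squares of
#' `log(normalized expression + pseudocount)` on `log(age)`, with the
#' two-sided t-test p-value of the slope. The ranking score is
#' `-log10(pv) * sgn(slope)` (zero when the slope is zero), so genes rising
#' with age rank at the top and genes falling with age at the bottom.
#'
#' @param norm gene x sample matrix of normalized pseudo-bulk expression.
#' @param ages positive ages per sample (>= 3 samples with >= 2 distinct
#'   ages required; identical ages are an error).
#' @param pseudocount added before the log (default 1 on the normalized
#'   scale).
#' @return data.frame: `gene_id`, `slope`, `pv`, `rank_score`, ordered as
#'   the input genes.
#' @export
age_model <- function(norm, ages, pseudocount = 1) {
  m <- as.matrix(norm)
  n <- ncol(m)
  assert_that(length(ages) == n, "one age per sample is required")
  assert_that(n >= 3, "need >= 3 samples")
  assert_that(all(ages > 0), "ages must be positive")
  x <- log(ages)
  assert_that(stats::var(x) > 0, "no age contrast (identical ages)")
  Y <- log(m + pseudocount)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.numeric(Y %*% xc) / sxx
  # constant genes carry no association: slope 0, p 1 by convention
  const <- rowSums((Y - rowMeans(Y))^2) < 1e-20
  slope[const] <- 0
  fitted_dev <- outer(slope, xc)                   # centered fitted values
  resid <- Y - rowMeans(Y) - fitted_dev
  rss <- rowSums(resid^2)
  df <- n - 2
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tstat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
  pv <- 2 * stats::pt(-abs(tstat), df)
  pv <- pmin(pmax(pv, .Machine$double.xmin), 1)
  pv[const] <- 1
  score <- ifelse(slope == 0, 0, -log10(pv) * sign(slope))
  data.frame(gene_id = rownames(m), slope = slope, pv = pv,
             rank_score = score, row.names = NULL, stringsAsFactors = FALSE)
}

# weighted Kolmogorov-Smirnov enrichment score for a set of positions in a
# ranking; absw is |score|^weight aligned with the ranking order.
running_es <- function(pos, absw, N) {
  pos <- sort(pos)
  k <- length(pos)
  w <- absw[pos]
  NR <- sum(w)
  hit_cum <- if (NR > 0) cumsum(w) / NR else seq_len(k) / k
  miss_rate <- 1 / (N - k)
  after <- hit_cum - (pos - seq_len(k)) * miss_rate
  before <- c(0, hit_cum[-k]) - (pos - 1 - (seq_len(k) - 1)) * miss_rate
  cand <- c(after, before)
  es <- cand[which.max(abs(cand))]
  peak_hit <- which.max(abs(c(after, -Inf)))  # index into hits for leading edge
  list(es = es, after = after, before = before, pos = pos)
}

#' Preranked gene-set enrichment analysis with a permutation null
#'
#' Genes are sorted by descending score (ties broken by gene id for
#' determinism) and each set's enrichment score (ES) is the extreme of the
#' weighted Kolmogorov-Smirnov running sum (hit increments proportional to
#' `|score|^weight`, default weight 1). The null distribution comes from
#' `n_perm` seeded random same-size gene sets; the p-value is the fraction
#' of same-sign null ES at least as extreme in absolute value, floored at
#' `1/(n_perm + 1)`; NES is ES divided by the mean |null ES| of the same
#' sign; p-values are Benjamini-Hochberg adjusted across sets. Sets with
#' fewer than 3 genes in the universe are skipped with a warning.
#'
#' @param scores named numeric vector of per-gene signed scores.
#' @param sets named list of gene-id vectors.
#' @param n_perm number of null permutations (default 5,000).
#' @param seed RNG seed for the null draws.
#' @param weight hit-weight exponent on |score|.
#' @return data.frame: `set`, `size`, `es`, `nes`, `p`, `p_adj`,
#'   `leading_edge` (comma-joined gene ids).
#' @export
preranked_gsea <- function(scores, sets, n_perm = 5000L, seed = 1L,
                           weight = 1) {
  assert_that(all(is.finite(scores)), "scores must be finite")
  ord <- order(-scores, names(scores))
  ranked <- names(scores)[ord]
  s_ranked <- scores[ord]
  N <- length(ranked)
  absw <- abs(s_ranked)^weight
  rank_of <- stats::setNames(seq_len(N), ranked)

  use <- vapply(sets, function(g) sum(g %in% ranked) >= 3, logical(1))
  if (any(!use))
    warning("skipping set(s) with < 3 genes in the universe: ",
            paste(names(sets)[!use], collapse = ", "), call. = FALSE)
  sets <- sets[use]
  if (!length(sets))
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), p_adj = numeric(),
                      leading_edge = character()))
  sizes <- vapply(sets, function(g) sum(g %in% ranked), integer(1))

  # shared null ES per distinct set size
  null_by_size <- list()
  for (k in sort(unique(sizes))) {
    null_by_size[[as.character(k)]] <- with_seed(child_seed(seed, k), {
      vapply(seq_len(n_perm), function(i) {
        running_es(sample.int(N, k), absw, N)$es
      }, numeric(1))
    })
  }

  res <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], ranked)
    pos <- unname(rank_of[members])
    r <- running_es(pos, absw, N)
    es <- r$es
    null_es <- null_by_size[[as.character(length(pos))]]
    same <- null_es[sign(null_es) == sign(es)]
    p <- if (length(same)) mean(abs(same) >= abs(es)) else 0
    p <- max(p, 1 / (n_perm + 1))
    denom <- if (length(same)) mean(abs(same)) else mean(abs(null_es))
    nes <- if (denom > 0) es / denom else 0
    ordered_pos <- sort(pos)
    if (es >= 0) {
      peak <- which.max(r$after)
      le <- ranked[ordered_pos[seq_len(peak)]]
    } else {
      peak <- which.min(r$before)
      le <- ranked[ordered_pos[seq(peak, length(ordered_pos))]]
    }
    data.frame(set = nm, size = length(pos), es = es, nes = nes, p = p,
               leading_edge = paste(le, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- adjust_p(out$p, "bh")
  out[, c("set", "size", "es", "nes", "p", "p_adj", "leading_edge")]
}

#' PCA of gene-level signature scores
#'
#' Column-centered principal component analysis (via SVD) of a gene x
#' signature score matrix restricted to genes present (non-missing) in all
#' signatures; each signature gets coordinates in PC space, with variance
#' explained per component.
#'
#' @param score_mat gene x signature numeric matrix (>= 2 signatures); rows
#'   with any `NA` are dropped.
#' @return list: `coordinates` (signature x PC), `var_explained`
#'   (fractions), `n_genes_used`.
#' @export
signature_pca <- function(score_mat) {
  m <- as.matrix(score_mat)
  assert_that(ncol(m) >= 2, "need >= 2 signatures")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  assert_that(nrow(m) >= 2, "fewer than 2 genes shared by all signatures")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = pc$x, var_explained = ve, n_genes_used = nrow(m))
}
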