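#' Cell-type composition across samples and conditions
#'
#' Computes per-sample cell-type counts and fractions (fractions sum to one
#' within each sample) and, when more than one condition is present, tests
#' each cell type's per-sample fractions across conditions: Welch's t-test
#' for two conditions, one-way ANOVA with Tukey HSD for three or more.
#'
#' @param counts an [annotated_counts()] (or its `cell_meta` data.frame).
#' @return list with `table` (sample_id, condition, tissue, n_cells,
#'   fraction) and `tests` (per cell type; `NULL` with a single condition).
#' @export
composition <- function(counts) {
  meta <- if (inherits(counts, "annotated_counts")) counts$cell_meta else counts
  tab <- as.data.frame(table(sample_id = meta$sample_id, tissue = meta$tissue),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n_cells"
  totals <- tapply(tab$n_cells, tab$sample_id, sum)
  empty <- names(totals)[totals == 0]
  if (length(empty)) {
    warning("sample(s) with zero cells excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
    tab <- tab[!tab$sample_id %in% empty, ]
    totals <- totals[!names(totals) %in% empty]
  }
  tab$fraction <- tab$n_cells / as.numeric(totals[tab$sample_id])
  tab$condition <- meta$condition[match(tab$sample_id, meta$sample_id)]

  conditions <- unique(tab$condition)
  tests <- NULL
  if (length(conditions) >= 2) {
    tests <- list()
    for (ct in unique(tab$tissue)) {
      sub <- tab[tab$tissue == ct, ]
      groups <- split(sub$fraction, sub$condition)
      groups <- groups[lengths(groups) >= 2]
      if (length(groups) < 2) next
      if (length(groups) == 2) {
        res <- welch_t(groups[[1]], groups[[2]])
        tests[[ct]] <- data.frame(
          tissue = ct, comparison = paste(names(groups), collapse = " vs "),
          statistic = res$statistic, p = res$p, method = res$method,
          stringsAsFactors = FALSE)
      } else {
        res <- anova_tukey(groups)
        tests[[ct]] <- data.frame(
          tissue = ct, comparison = res$pairs$comparison,
          statistic = res$pairs$diff, p = res$pairs$p_adj,
          method = "anova_tukey", stringsAsFactors = FALSE)
      }
    }
    tests <- do.call(rbind, tests)
    if (!is.null(tests)) rownames(tests) <- NULL
  }
  list(table = tab, tests = tests)
}

#' Fraction of marker-positive cells per sample
#'
#' @param norm gene x cell matrix of normalized expression.
#' @param sample_ids sample label per cell.
#' @param marker gene id present in `norm`.
#' @param threshold positivity threshold on normalized expression
#'   (strictly greater; default 0, i.e. any detection).
#' @return data.frame: `sample_id`, `n_cells`, `fraction_positive`.
#' @export
marker_positive_fraction <- function(norm, sample_ids, marker, threshold = 0) {
  assert_that(marker %in% rownames(norm),
              paste0("marker '", marker, "' absent from the panel"))
  assert_that(length(sample_ids) == ncol(norm),
              "one sample label per cell is required")
  pos <- as.numeric(norm[marker, ]) > threshold
  agg <- tapply(pos, sample_ids, function(x) c(n = length(x), f = mean(x)))
  data.frame(sample_id = names(agg),
             n_cells = vapply(agg, `[[`, numeric(1), "n"),
             fraction_positive = vapply(agg, `[[`, numeric(1), "f"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cell-cycle module scores and phase assignment
#'
#' For each marker panel (S and G2M), the score of a cell is the mean
#' normalized expression of the panel genes minus the mean expression of a
#' seeded control gene set, drawn per panel gene from its average-expression
#' bin (genes ranked by mean expression across cells and cut into
#' `n_bins` equal-frequency bins; `n_ctrl` controls per panel gene, sampled
#' within bin). A cell is assigned the phase of its larger score when
#' either score is positive, otherwise G1.
#'
#' @param norm gene x cell matrix of normalized expression.
#' @param s_genes,g2m_genes marker panels (must intersect the matrix rows).
#' @param n_bins number of equal-frequency average-expression bins.
#' @param n_ctrl control genes sampled per panel gene.
#' @param seed RNG seed for the control draws.
#' @return data.frame: `cell_id`, `s_score`, `g2m_score`,
#'   `phase` in {G1, S, G2M}.
#' @export
cell_cycle_score <- function(norm, s_genes, g2m_genes, n_bins = 24L,
                             n_ctrl = 100L, seed = 1L) {
  assert_that(length(s_genes) > 0 && length(g2m_genes) > 0,
              "marker lists must be non-empty")
  s_genes <- intersect(s_genes, rownames(norm))
  g2m_genes <- intersect(g2m_genes, rownames(norm))
  assert_that(length(s_genes) > 0, "no S-panel genes present in the matrix")
  assert_that(length(g2m_genes) > 0, "no G2M-panel genes present in the matrix")

  avg <- Matrix::rowMeans(norm)
  ng <- length(avg)
  n_bins <- min(n_bins, ng)
  bin <- ceiling(rank(avg, ties.method = "first") / (ng / n_bins))
  genes_by_bin <- split(rownames(norm), bin)

  score_set <- function(set, stream) {
    ctrl <- with_seed(child_seed(seed, stream), {
      unique(unlist(lapply(set, function(g) {
        candidates <- setdiff(genes_by_bin[[as.character(bin[g])]], set)
        if (!length(candidates)) return(character())
        sample(candidates, min(n_ctrl, length(candidates)))
      })))
    })
    set_mean <- Matrix::colMeans(norm[set, , drop = FALSE])
    ctrl_mean <- if (length(ctrl))
      Matrix::colMeans(norm[ctrl, , drop = FALSE]) else 0
    set_mean - ctrl_mean
  }
  names(bin) <- rownames(norm)
  s_score <- score_set(s_genes, 1L)
  g2m_score <- score_set(g2m_genes, 2L)

  phase <- rep("G1", ncol(norm))
  pos <- pmax(s_score, g2m_score) > 0
  phase[pos & s_score >= g2m_score] <- "S"
  phase[pos & g2m_score > s_score] <- "G2M"
  data.frame(cell_id = colnames(norm), s_score = as.numeric(s_score),
             g2m_score = as.numeric(g2m_score), phase = phase,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of cells in G1 per group
#'
#' @param calls output of [cell_cycle_score()].
#' @param groups group label per cell (e.g. subtype x sample), aligned with
#'   `calls` rows.
#' @return data.frame: `group`, `n_cells`, `g1_fraction`. Empty groups are
#'   skipped with a warning.
#' @export
g1_fraction_by_group <- function(calls, groups) {
  assert_that(length(groups) == nrow(calls),
              "one group label per cell is required")
  groups <- as.character(groups)
  lv <- unique(groups)
  res <- lapply(lv, function(g) {
    sel <- groups == g
    if (!any(sel)) { warning("empty group skipped: ", g); return(NULL) }
    data.frame(group = g, n_cells = sum(sel),
               g1_fraction = mean(calls$phase[sel] == "G1"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
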