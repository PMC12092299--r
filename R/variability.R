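#' Library-size size factors
#'
#' Per-cell size factor: total UMI divided by the geometric mean of totals,
#' so factors average ~1 on the log scale and dividing counts by them
#' equalizes library sizes.
#'
#' @param counts an [annotated_counts()] or gene x cell count matrix.
#' @return named positive numeric vector, one factor per cell.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "annotated_counts")) counts$matrix else counts
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop("cell(s) with zero total counts", call. = FALSE)
  geo <- exp(mean(log(totals)))
  stats::setNames(totals / geo, colnames(m))
}

#' Normalize by size factors and log transform
#'
#' `value = ln(1 + count / size_factor)`; the normalization used for the
#' variance decomposition.
#'
#' @param counts an [annotated_counts()] or gene x cell count matrix.
#' @param sf size factors from [size_factors()] (computed if missing).
#' @return sparse gene x cell matrix.
#' @export
normalize_by_size_factors <- function(counts, sf = NULL) {
  m <- if (inherits(counts, "annotated_counts")) counts$matrix else
    as_csparse(counts)
  if (is.null(sf)) sf <- size_factors(m)
  norm <- m %*% Matrix::Diagonal(x = 1 / sf)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  norm
}

#' Decompose per-gene variance into trend (technical) and residual
#' (biological) components
#'
#' Computes each gene's mean and variance of log-normalized expression,
#' fits a smooth non-negative mean-variance trend (running median over
#' mean-ordered genes, window a fixed fraction of the gene count, clipped
#' at zero), and defines the biological component as the residual from the
#' trend. Residuals may be negative.
#'
#' @param norm gene x cell matrix of log-normalized expression.
#' @param window_frac running-median window as a fraction of the gene count.
#' @param min_genes minimum genes needed to fit the trend.
#' @return data.frame: `gene_id`, `mean_expr`, `total_var`, `trend_var`,
#'   `bio_var` (`total_var - trend_var`).
#' @export
decompose_variance <- function(norm, window_frac = 0.2, min_genes = 20L) {
  nc <- ncol(norm)
  assert_that(nc >= 2, "need >= 2 cells")
  ng <- nrow(norm)
  assert_that(ng >= min_genes,
              paste0("too few genes (", ng, ") to fit a mean-variance trend"))
  rs <- Matrix::rowSums(norm)
  rs2 <- Matrix::rowSums(norm^2)
  mu <- rs / nc
  v <- pmax(0, (rs2 - rs^2 / nc) / (nc - 1))

  ord <- order(mu)
  k <- max(3L, round(window_frac * ng))
  if (k %% 2 == 0) k <- k + 1L
  trend_sorted <- stats::runmed(v[ord], k, endrule = "median")
  trend <- numeric(ng)
  trend[ord] <- pmax(0, trend_sorted)

  data.frame(gene_id = rownames(norm), mean_expr = mu, total_var = v,
             trend_var = trend, bio_var = v - trend,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mean biological variability per group
#'
#' Summarizes [decompose_variance()] tables (one per tissue x sample group)
#' into a single mean biological-variance scalar per group, the quantity
#' compared across conditions downstream (e.g. with [welch_t()]).
#'
#' @param tables named list of `decompose_variance` data.frames.
#' @return data.frame: `group`, `n_genes`, `mean_bio_var`.
#' @export
variability_summary <- function(tables) {
  assert_that(is.list(tables) && length(tables) > 0, "need >= 1 table")
  if (is.null(names(tables))) names(tables) <- seq_along(tables)
  data.frame(
    group = names(tables),
    n_genes = vapply(tables, nrow, integer(1)),
    mean_bio_var = vapply(tables, function(t) mean(t$bio_var), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-(tissue x sample) variability analysis
#'
#' Convenience wrapper: for every tissue x sample group with enough cells,
#' filters genes by a minimal detection fraction, normalizes by size
#' factors, decomposes the variance, and summarizes.
#'
#' @param counts an [annotated_counts()] (QC-filtered).
#' @param min_cells skip groups smaller than this.
#' @param min_detect_frac keep genes detected in at least this fraction of
#'   the group's cells.
#' @param window_frac passed to [decompose_variance()].
#' @return list with `tables` (per-group gene tables) and `summary`
#'   (a [variability_summary()] data.frame with tissue/sample/condition
#'   columns attached).
#' @export
variability_by_group <- function(counts, min_cells = 50L,
                                 min_detect_frac = 0.01,
                                 window_frac = 0.2) {
  stopifnot(inherits(counts, "annotated_counts"))
  meta <- counts$cell_meta
  key <- paste(meta$tissue, meta$sample_id, sep = "|")
  tables <- list()
  for (g in unique(key)) {
    cells <- which(key == g)
    if (length(cells) < min_cells) next
    m <- counts$matrix[, cells, drop = FALSE]
    keep <- Matrix::rowSums(m > 0) >= min_detect_frac * ncol(m)
    if (sum(keep) < 20) next
    norm <- normalize_by_size_factors(m[keep, , drop = FALSE])
    tables[[g]] <- decompose_variance(norm, window_frac = window_frac)
  }
  summ <- variability_summary(tables)
  parts <- do.call(rbind, strsplit(summ$group, "|", fixed = TRUE))
  summ$tissue <- parts[, 1]
  summ$sample_id <- parts[, 2]
  summ$condition <- meta$condition[match(summ$sample_id, meta$sample_id)]
  list(tables = tables, summary = summ)
}
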