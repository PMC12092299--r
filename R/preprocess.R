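#' Quality-control filter on cells
#'
#' Removes cells with fewer detected genes than `min_genes_per_cell`
#' (strictly fewer: a cell at the threshold is retained) or with a
#' mitochondrial UMI fraction above `max_mito_fraction`. Per-rule removal
#' counts are attached as the `"removed"` attribute. Idempotent.
#'
#' @param counts an [annotated_counts()] with QC metric columns.
#' @param cfg a [run_config()]; `cfg$qc` supplies the thresholds.
#' @return filtered `annotated_counts`.
#' @export
qc_filter <- function(counts, cfg = run_config()) {
  stopifnot(inherits(counts, "annotated_counts"))
  meta <- counts$cell_meta
  low_genes <- meta$n_genes_detected < cfg$qc$min_genes_per_cell
  high_mito <- meta$mito_fraction > cfg$qc$max_mito_fraction
  keep <- !(low_genes | high_mito)
  if (!any(keep))
    stop("QC removed every cell; review min_genes_per_cell/max_mito_fraction",
         call. = FALSE)
  out <- subset_cells(counts, which(keep))
  attr(out, "removed") <- c(low_genes = sum(low_genes),
                            high_mito = sum(high_mito & !low_genes),
                            kept = sum(keep))
  out
}

#' Flag doublet-like cells with extremely high UMI totals
#'
#' Within each sample, flags cells whose total UMI exceeds
#' `median + k_mad * MAD` of that sample's totals. A sample whose MAD is
#' zero (e.g. identical totals) yields no flags. Cells are flagged, not
#' removed, unless the caller drops them.
#'
#' @param counts an [annotated_counts()] with >= 10 cells.
#' @param k_mad MAD multiplier (default 5).
#' @return character vector of flagged cell ids (possibly empty).
#' @export
flag_high_umi_outliers <- function(counts, k_mad = 5) {
  stopifnot(inherits(counts, "annotated_counts"))
  meta <- counts$cell_meta
  assert_that(nrow(meta) >= 10, "need >= 10 cells to estimate outliers")
  flagged <- character()
  for (s in unique(meta$sample_id)) {
    rows <- meta$sample_id == s
    tot <- meta$total_umi[rows]
    m <- stats::median(tot)
    md <- stats::mad(tot)
    if (md == 0) next
    flagged <- c(flagged, meta$cell_id[rows][tot > m + k_mad * md])
  }
  flagged
}

#' Library-size normalization and log transform
#'
#' Per cell, counts are scaled to a common library size and log
#' transformed: `value = ln(1 + count * scale / total_umi)`. Zero counts
#' map exactly to zero and the result is invariant to rescaling all of a
#' cell's counts.
#'
#' @param counts an [annotated_counts()] or a gene x cell count matrix.
#' @param scale target library size (default 10,000).
#' @return sparse gene x cell matrix of normalized log expression.
#' @export
normalize_log <- function(counts, scale = 1e4) {
  m <- if (inherits(counts, "annotated_counts")) counts$matrix else
    as_csparse(counts)
  totals <- Matrix::colSums(m)
  if (any(totals == 0))
    stop("cell(s) with zero total UMI: ",
         paste(utils::head(colnames(m)[totals == 0], 5), collapse = ", "),
         " (QC should have removed them)", call. = FALSE)
  norm <- m %*% Matrix::Diagonal(x = scale / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(m)
  norm
}

#' Select highly variable genes by standard deviation
#'
#' Ranks genes by the standard deviation of their normalized log expression
#' across cells (descending), breaking ties lexicographically by gene id,
#' and returns the top `n`.
#'
#' @param norm gene x cell matrix of normalized log expression.
#' @param n panel size (default 2,000). If `n` exceeds the gene count, all
#'   genes are returned with a warning.
#' @return an `hvg_panel`: data.frame of `gene_id` and `sd`, ordered by
#'   descending `sd`.
#' @export
select_hvg <- function(norm, n = 2000L) {
  nc <- ncol(norm)
  assert_that(nc >= 2, "need >= 2 cells to compute standard deviations")
  rs <- Matrix::rowSums(norm)
  rs2 <- Matrix::rowSums(norm^2)
  v <- pmax(0, (rs2 - rs^2 / nc) / (nc - 1))
  sds <- sqrt(v)
  ids <- rownames(norm)
  if (n > length(ids)) {
    warning("requested ", n, " HVGs but only ", length(ids),
            " genes available; returning all", call. = FALSE)
    n <- length(ids)
  }
  ord <- order(-sds, ids)
  sel <- ord[seq_len(n)]
  structure(data.frame(gene_id = ids[sel], sd = sds[sel],
                       stringsAsFactors = FALSE),
            class = c("hvg_panel", "data.frame"))
}
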