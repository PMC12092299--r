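#' Run the full aging-and-rejuvenation analysis pipeline
#'
#' Executes the stages in a fixed order on an annotated count matrix (or on
#' counts freshly simulated from a design): cell QC and high-UMI flagging;
#' normalization and HVG selection; per-(tissue x sample) mean-mutual-
#' distance entropy; cell-to-cell variability decomposition; composition
#' analysis with condition tests; cell-cycle scoring and G1 fractions;
#' per-tissue old-vs-young differential expression, age-associated gene
#' (PAG) calling and rejuvenation-reversal scoring against the
#' old-vs-regenerated contrast; and the comparative-signature stage
#' (pseudo-bulk aggregation, detection filtering, RLE normalization, the
#' per-gene log-log age model fitted on young and old samples, and
#' preranked GSEA). Every stage draws its randomness from `cfg$seed`, so a
#' rerun with the same inputs reproduces the report exactly.
#'
#' @param counts an [annotated_counts()]; or `NULL` to simulate from
#'   `design`.
#' @param design a [simulation_design()] used when `counts` is `NULL`
#'   (default design if missing).
#' @param truth optional ground truth (attached to the report when
#'   simulating).
#' @param cfg a [run_config()].
#' @param s_genes,g2m_genes cell-cycle marker panels; default to the
#'   simulation's planted panels when available, otherwise the cell-cycle
#'   stage is skipped.
#' @param gene_sets named list of gene sets for GSEA; when `NULL`, fixture
#'   sets (one drawn from the top of the age ranking plus random sets) are
#'   built from the measured universe.
#' @param output_dir when non-`NULL`, report tables are written there as
#'   TSV/JSON.
#' @return a `screjuv_report` list (see sections in the package vignette).
#' @export
run_pipeline <- function(counts = NULL, design = NULL, truth = NULL,
                         cfg = run_config(), s_genes = NULL, g2m_genes = NULL,
                         gene_sets = NULL, output_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(counts)) {
    if (is.null(design)) design <- simulation_design(seed = cfg$seed)
    sim <- stage("simulate", simulate_counts(design))
    counts <- sim$counts
    truth <- sim$truth
  }
  stopifnot(inherits(counts, "annotated_counts"))
  if (is.null(s_genes) && !is.null(truth)) s_genes <- truth$s_genes
  if (is.null(g2m_genes) && !is.null(truth)) g2m_genes <- truth$g2m_genes

  qc <- stage("qc", qc_filter(counts, cfg))
  flags <- stage("qc", flag_high_umi_outliers(qc, cfg$qc$high_umi_mad_k))
  if (isTRUE(cfg$qc$remove_high_umi) && length(flags))
    qc <- subset_cells(qc, setdiff(qc$cell_ids, flags))
  qc_summary <- list(n_input = ncol(counts$matrix), n_kept = ncol(qc$matrix),
                     removed = attr(qc, "removed"), high_umi_flagged = flags)

  norm <- stage("normalize", normalize_log(qc, cfg$normalization$scale_factor))
  hvg <- stage("hvg", select_hvg(norm, cfg$hvg$n_hvg))

  meta <- qc$cell_meta
  group_key <- paste(meta$tissue, meta$sample_id, sep = "|")
  entropy_tab <- stage("entropy",
    group_entropy(norm[hvg$gene_id, , drop = FALSE], group_key,
                  max_pairs = cfg$entropy$max_pairs, seed = cfg$seed))
  parts <- do.call(rbind, strsplit(entropy_tab$group, "|", fixed = TRUE))
  entropy_tab$tissue <- parts[, 1]
  entropy_tab$sample_id <- parts[, 2]
  entropy_tab$condition <- meta$condition[match(entropy_tab$sample_id,
                                                meta$sample_id)]

  variability <- stage("variability",
    variability_by_group(qc, min_detect_frac = cfg$variability$min_detect_frac,
                         window_frac = cfg$variability$trend_window_frac))

  comp <- stage("composition", composition(qc))

  cellcycle <- NULL
  if (!is.null(s_genes) && !is.null(g2m_genes)) {
    calls <- stage("cellcycle",
      cell_cycle_score(norm, s_genes, g2m_genes,
                       n_bins = cfg$cellcycle$n_bins,
                       n_ctrl = cfg$cellcycle$n_ctrl, seed = cfg$seed))
    g1 <- g1_fraction_by_group(calls, group_key)
    cellcycle <- list(calls = calls, g1_fractions = g1)
  }

  # per-tissue DE, PAG calling and reversal scoring
  pag_tables <- list(); reversal <- list(); de_tables <- list()
  for (ct in unique(meta$tissue)) {
    in_ct <- meta$tissue == ct
    old_cells <- meta$cell_id[in_ct & meta$condition == "old"]
    young_cells <- meta$cell_id[in_ct & meta$condition == "young"]
    regen_cells <- meta$cell_id[in_ct & meta$condition == "regenerated"]
    if (length(old_cells) < 3 || length(young_cells) < 3) next
    de_age <- stage("pag",
      differential_expression(norm, old_cells, young_cells,
                              min_pct = cfg$de$min_pct,
                              pseudocount = cfg$de$pseudocount))
    pags <- call_pags(de_age, cfg$de$log2fc_min, cfg$de$adj_p_max, tissue = ct)
    pag_tables[[ct]] <- pags
    de_tables[[ct]] <- list(old_vs_young = de_age)
    if (length(regen_cells) >= 3) {
      de_regen <- stage("reversal",
        differential_expression(norm, old_cells, regen_cells,
                                min_pct = cfg$de$min_pct,
                                pseudocount = cfg$de$pseudocount))
      de_tables[[ct]]$old_vs_regenerated <- de_regen
      reversal[[ct]] <- reversal_score(pags, de_regen,
                                       cfg$de$log2fc_min, cfg$de$adj_p_max,
                                       mode = cfg$reversal$mode)
    }
  }

  # comparative-signature stage on sample-level pseudo-bulk
  signatures <- stage("signatures", {
    pb <- aggregate_pseudobulk(qc, "sample")
    fm <- filter_and_map(pb, NULL, cfg$pseudobulk$min_umi,
                         cfg$pseudobulk$min_sample_fraction)
    rle <- rle_normalize(fm)
    aging <- fm$covariates$condition %in% c("young", "old")
    assoc <- age_model(rle$matrix[, aging, drop = FALSE],
                       fm$covariates$age_months[aging],
                       pseudocount = cfg$pseudobulk$pseudocount)
    scores <- stats::setNames(assoc$rank_score, assoc$gene_id)
    if (is.null(gene_sets)) {
      ranked_ids <- assoc$gene_id[order(-assoc$rank_score,
                                        -abs(assoc$slope), assoc$gene_id)]
      gene_sets <- c(list(top_aging = utils::head(ranked_ids, 20)),
                     with_seed(child_seed(cfg$seed, 77), {
                       out <- list()
                       for (i in 1:10)
                         out[[sprintf("random_%02d", i)]] <-
                           sample(assoc$gene_id, 20)
                       out
                     }))
    }
    gsea <- preranked_gsea(scores, gene_sets,
                           n_perm = cfg$gsea$n_permutations,
                           seed = cfg$seed, weight = cfg$gsea$weight)
    corr <- condition_correlation(fm$matrix, fm$covariates$condition)
    list(pseudobulk = fm, size_factors = rle$size_factors,
         association = assoc, gsea = gsea, correlation = corr)
  })

  report <- structure(list(
    config = cfg, seed = cfg$seed,
    qc = qc_summary, hvg = hvg, entropy = entropy_tab,
    variability = variability$summary,
    composition = comp, cellcycle = cellcycle,
    de = de_tables, pags = pag_tables, reversal = reversal,
    signatures = signatures, truth = truth),
    class = "screjuv_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.screjuv_report <- function(x, ...) {
  cat("<screjuv_report>\n")
  cat(sprintf("  cells kept after QC: %d of %d\n", x$qc$n_kept, x$qc$n_input))
  cat(sprintf("  entropy groups: %d\n", nrow(x$entropy)))
  cat(sprintf("  tissues with PAG calls: %s\n",
              paste(names(x$pags), collapse = ", ")))
  for (ct in names(x$reversal))
    cat(sprintf("  %s: %d PAGs, %.1f%% reversed\n", ct,
                x$reversal[[ct]]$n_up + x$reversal[[ct]]$n_down,
                x$reversal[[ct]]$pct_reversed))
  invisible(x)
}

#' Write a pipeline report as TSV/JSON files
#'
#' @param report a `screjuv_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(report$entropy, "entropy.tsv")
  wt(report$variability, "variability.tsv")
  wt(report$composition$table, "composition.tsv")
  if (!is.null(report$composition$tests))
    wt(report$composition$tests, "composition_tests.tsv")
  if (!is.null(report$cellcycle)) {
    wt(report$cellcycle$calls, "cellcycle_calls.tsv")
    wt(report$cellcycle$g1_fractions, "cellcycle_g1.tsv")
  }
  for (ct in names(report$pags))
    wt(report$pags[[ct]], paste0("pags_", ct, ".tsv"))
  rev_df <- do.call(rbind, lapply(report$reversal, function(r)
    data.frame(tissue = r$tissue, n_up = r$n_up, n_down = r$n_down,
               n_up_reversed = r$n_up_reversed,
               n_down_reversed = r$n_down_reversed,
               pct_up_reversed = r$pct_up_reversed,
               pct_down_reversed = r$pct_down_reversed,
               pct_reversed = r$pct_reversed, mode = r$mode)))
  if (!is.null(rev_df)) wt(rev_df, "reversal.tsv")
  wt(report$signatures$association, "age_association.tsv")
  wt(report$signatures$gsea[, setdiff(names(report$signatures$gsea),
                                      "leading_edge")], "gsea.tsv")
  jsonlite::write_json(
    list(seed = report$seed,
         qc = report$qc[c("n_input", "n_kept")],
         config = unclass(report$config)),
    file.path(dir, "run_info.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
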