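#!/usr/bin/env Rscript
# Stage 2: quality control, normalization, HVG panel.
#
# Removes cells with < 500 detected genes or > 20% mitochondrial UMIs,
# flags doublet-like high-UMI cells (median + 5 MAD per sample), scales
# each cell to 10,000 counts with a log transform, and selects the 2,000
# highest-SD genes as the HVG panel.

suppressPackageStartupMessages(library(screjuv))

cfg <- run_config(seed = 1L)
counts <- read_counts("results/data")
truth <- read_ground_truth("results/data/ground_truth.json")

qc <- qc_filter(counts, cfg)
removed <- attr(qc, "removed")
flags <- flag_high_umi_outliers(qc, cfg$qc$high_umi_mad_k)
cat(sprintf("QC: kept %d of %d cells (%d low-gene, %d high-mito removed)\n",
            ncol(qc$matrix), ncol(counts$matrix),
            removed[["low_genes"]], removed[["high_mito"]]))
cat(sprintf("high-UMI flags: %d cells (%d of %d planted doublets recalled)\n",
            length(flags), sum(truth$doublet_cells %in% flags),
            length(truth$doublet_cells)))
cat(sprintf("planted high-mito cells removed: %d of %d\n",
            sum(!truth$highmito_cells %in% qc$cell_ids),
            length(truth$highmito_cells)))

norm <- normalize_log(qc, cfg$normalization$scale_factor)
hvg <- select_hvg(norm, cfg$hvg$n_hvg)
cat(sprintf("HVG panel: %d genes, SD range %.3f-%.3f\n",
            nrow(hvg), min(hvg$sd), max(hvg$sd)))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write_counts(qc, "results/data_qc")
write.table(hvg, "results/tables/hvg_panel.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
qc_report <- data.frame(rule = names(removed), cells = as.integer(removed))
write.table(qc_report, "results/tables/qc_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(flags, "results/tables/high_umi_flags.txt")
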