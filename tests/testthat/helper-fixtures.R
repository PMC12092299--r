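# shared fixture builders; everything is generated in code at test time

# minimal two-condition design on one tissue
tiny_design <- function(n_genes = 400L, cells = 60L, n_up = 20L, n_down = 20L,
                        effect = 1, reversal = 0, conditions = 2L, seed = 1L) {
  samples <- if (conditions == 2L)
    data.frame(sample_id = c("y1", "y2", "o1", "o2"),
               condition = c("young", "young", "old", "old"),
               age_months = c(6, 6, 24, 24))
  else
    data.frame(sample_id = c("y1", "y2", "o1", "o2", "r1", "r2"),
               condition = c("young", "young", "old", "old",
                             "regenerated", "regenerated"),
               age_months = c(6, 6, 24, 24, 24, 24))
  simulation_design(
    n_genes = n_genes, cell_types = "tissue", samples = samples,
    cells_per_sample_per_type = cells,
    pag_spec = list(tissue = list(n_up = n_up, n_down = n_down,
                                  effect_log2fc = effect)),
    reversal_fraction = reversal, doublet_fraction = 0,
    mito_gene_fraction = 0.02, seed = seed)
}

# dense matrix of normalized values with named dims
named_matrix <- function(x, ngene, ncell, prefix = c("g", "c")) {
  matrix(x, ngene, ncell,
         dimnames = list(sprintf("%s%04d", prefix[1], seq_len(ngene)),
                         sprintf("%s%04d", prefix[2], seq_len(ncell))))
}

# relaxed QC config for small simulated fixtures (few hundred genes)
lenient_qc <- function(...) run_config(qc = list(min_genes_per_cell = 0L), ...)
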