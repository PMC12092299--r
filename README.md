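# screjuv — single-cell analysis of aging and its reversal by regeneration

`screjuv` is an R package and analysis workflow for a question raised by
highly regenerative animals such as planarians: when an aged animal
regenerates a tissue, does the new tissue return to a transcriptomically
young state? Given single-cell RNA-seq UMI counts from **young**, **old**
and **regenerated** individuals, the package

- performs cell QC (≥ 500 detected genes, mitochondrial-fraction cutoff,
  high-UMI doublet flagging), library-size normalization, and selection of
  the top-2,000-SD highly variable genes (HVGs);
- quantifies expression stochasticity per cell type and sample with the
  **mean mutual distance**: for cells with normalized HVG vectors
  *v₁ … vₛ*, the mean of *d(vᵢ, vⱼ) = |vᵢ − vⱼ|* over all pairs
  *i < j*, an entropy-like statistic calibrated against its Gaussian
  closed forms *H = D/2 (1 + ln 2π) + ½ ln det Σ* and
  *E|x − y| ≲ √(2 Tr Σ)*;
- decomposes cell-to-cell variability per gene into a mean–variance-trend
  (technical) part and a residual (biological) part;
- analyses cell-type composition and cell-cycle phases (binned-control
  S/G2M module scores, G1 fractions);
- calls **age-associated genes** per tissue (Wilcoxon rank-sum old vs
  young, Bonferroni; |log₂FC| > 0.25, adjusted p < 0.05) and scores their
  **reversal**: a gene is rejuvenated when its old-vs-regenerated change
  has the same sign as its old-vs-young change;
- builds a pseudo-bulk aging signature — UMI sums per sample, ≥ 10 UMIs in
  ≥ 20 % of samples, relative-log-expression normalization, per-gene OLS
  of log expression on log age — ranks genes by *−log₁₀(p) · sgn(slope)*,
  and runs preranked permutation GSEA (5,000 gene-set permutations,
  BH-adjusted, cutoff 0.1) plus cross-signature PCA.

Every stage is validated on a negative-binomial simulator with **planted
ground truth** (per-tissue log₂ fold changes, reversal fractions,
proportion shifts, cell-cycle programs, high-mito and doublet-like cells),
so recovery can be measured exactly. See
`vignettes/aging-rejuvenation-methods.Rmd` for the full methods account.

## Worked example

Simulate one neoblast tissue with 50 up- and 50 down-regulated aging genes
(|log₂FC| = 1), 70 % of them restored to young expression after
regeneration, then recover both numbers:

```r
library(screjuv)

samples <- data.frame(
  sample_id  = c("y1", "y2", "o1", "o2", "r1", "r2"),
  condition  = c("young", "young", "old", "old", "regenerated", "regenerated"),
  age_months = c(6, 6, 24, 24, 24, 24))
design <- simulation_design(
  n_genes = 1000, cell_types = "neoblast", samples = samples,
  cells_per_sample_per_type = 150,
  pag_spec = list(neoblast = list(n_up = 50, n_down = 50, effect_log2fc = 1)),
  reversal_fraction = 0.7, seed = 1)
sim  <- simulate_counts(design)
qc   <- qc_filter(sim$counts, run_config(qc = list(min_genes_per_cell = 100L)))
norm <- normalize_log(qc)
meta <- qc$cell_meta

de_age   <- differential_expression(norm, meta$cell_id[meta$condition == "old"],
                                    meta$cell_id[meta$condition == "young"])
de_regen <- differential_expression(norm, meta$cell_id[meta$condition == "old"],
                                    meta$cell_id[meta$condition == "regenerated"])
pags <- call_pags(de_age, tissue = "neoblast")
rv   <- reversal_score(pags, de_regen)
```

This prints (seed 1):

```
PAGs called: 94 (sensitivity 0.94)
reversed: 34 up + 30 down = 68.1% (planted 70%)
```

94 of the 100 planted aging genes are called at the stated thresholds, and
the strict-mode reversal percentage lands within two points of the planted
70 %. The per-group entropy statistic on the same data:

```r
ent <- group_entropy(norm[select_hvg(norm, 500)$gene_id, ],
                     paste(meta$tissue, meta$sample_id, sep = "|"), seed = 1)
head(ent[, c("group", "n_cells", "mean_mutual_distance")], 3)
#>         group n_cells mean_mutual_distance
#> 1 neoblast|y1     150             46.08165
#> 2 neoblast|y2     150             45.35444
#> 3 neoblast|o1     150             44.66941
```

Each row is one biological replicate's mean pairwise cell–cell distance
over the HVG panel — the unit compared across age groups.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/07_signatures.R` run the full study
on the default 13-sample, 4-tissue, ~6,000-cell synthetic dataset, each a
thin driver over the package that prints what it found and writes tables
under `results/tables/`. Run them in order from the repository root:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

Stage 6, for example, reports per-tissue PAG sensitivity of 1.0 and
pooled strict-mode reversal percentages of 66–70 % against the planted
70 %. `run_pipeline()` executes the same stages in one call and returns a
single report object.

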