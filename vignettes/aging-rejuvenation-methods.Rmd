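---
title: "Methods: quantifying transcriptomic aging and its reversal in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transcriptomic aging and its reversal in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screjuv)
```

# The scientific problem

Highly regenerative animals such as planarians appear to escape many
hallmarks of aging: amputation and regeneration can restore a youthful
head from an aged animal. `screjuv` implements the computational side of
that question for single-cell RNA-seq: given UMI count matrices from
young, old, and regenerated individuals, it asks

1. which genes change with age in each tissue (age-associated genes,
   "PAGs"),
2. whether regeneration reverses those changes gene by gene,
3. whether expression becomes noisier with age (an entropy-like
   stochasticity statistic on cell-cell distances),
4. how cell-type composition and cell-cycle state shift, and
5. how a pseudo-bulk aging signature compares with external signatures
   through preranked gene-set enrichment and PCA.

Because the pipeline's statistical behaviour cannot be validated on real
tissue (no ground truth is knowable there), every stage is exercised on a
negative-binomial simulator with planted truth. The simulator is
first-class, tested code: its defaults *are* the study conditions, and
the tests ask whether the pipeline recovers what was planted.

# The synthetic study and its assumptions

`simulation_design()` describes a multi-sample, multi-tissue experiment.
The default mirrors a head-sampling design across the life course: 13
samples — six young (5 or 7 months), four old (12–32 months) and three
regenerated (32 months chronological age after three
amputation–regeneration rounds) — with four tissues and ~115 cells per
sample per tissue (~6,000 cells over 2,000 genes). Age is measured in
months since fertilization and must be strictly positive.

The count model is negative binomial with a gene-level dispersion shared
across cells (`variance = mu + dispersion * mu^2`; dispersion 0.4 by
default, 0 gives Poisson). Per-gene baseline means are lognormal around
`baseline_mean` (default 0.5 UMI, sdlog 1), which yields the skewed
expression distribution typical of UMI data. Each cell carries a
lognormal library-size multiplier (sdlog 0.3) so that size-factor
normalization is non-trivially exercised.

Planted structure, all recorded in the returned ground truth:

* **Age effects.** Per tissue, `n_up`/`n_down` genes have their mean
  scaled by `2^(+-effect_log2fc)` in old samples. Effects are planted on
  genes at or above the median baseline mean: a fold change planted on a
  gene that is essentially never detected is unmeasurable by any method,
  and empirically age-associated genes are by construction detected
  genes.
* **Reversal.** A `reversal_fraction` of each tissue's planted genes has
  its regenerated-sample mean restored to the young level; the remainder
  retains the old level. With `reversal_fraction = 1` the regenerated
  and young generative means coincide exactly.
* **Composition.** Per-condition multipliers on cells per type.
* **Cell cycle.** Two disjoint marker panels (20 genes each); cells are
  assigned G1/S/G2M with probabilities 0.6/0.2/0.2 and matching-phase
  panel means are scaled by `2^2` (a 2-log2-unit program).
* **Artifacts.** Mitochondrial genes are an id prefix (`MT-`, 2% of
  genes); optional high-mito cells have mito means inflated to a target
  fraction; a `doublet_fraction` of cells receives a second,
  scale-matched count draw so their expected totals double.

What the simulator does **not** emulate: batch effects and ambient RNA,
gene–gene correlation beyond the planted programs, mean-dependent
dispersion trends, true doublets mixing two cell types, or realistic
gene identifiers and orthology. Passing tests therefore demonstrate the
pipeline's statistical correctness under a clean generative model, not
robustness to every artifact of real data.

# Preprocessing

Cells with fewer than 500 detected genes (strictly fewer; a cell at
exactly 500 is retained) or a mitochondrial fraction above 0.2 are
removed. The mito cutoff is a configuration value, not a constant — real
studies calibrate it per sample. Doublet-like cells are *flagged*, not
removed, when their total UMI exceeds the per-sample
`median + k * MAD` (k = 5); a zero MAD yields no flags. The MAD rule
trades recall for robustness: under the default lognormal library spread
(sdlog 0.3) only extreme totals are flagged, while at modest spread
(sdlog ~0.1) doubled-total cells are recalled at over 90% with k = 3 —
the regime the recall tests use.

Normalization is per-cell scaling to 10,000 counts followed by natural
`log1p`; zero counts map exactly to zero and the result is invariant to
rescaling a cell's counts. The HVG panel is the top 2,000 genes by
standard deviation of the normalized values (ties broken
lexicographically by gene id, so the panel is deterministic and
permutation-invariant).

# The entropy statistic

Each cell is a vector `v = (n_1, ..., n_G)` of normalized HVG
expression. For a group of cells (one cell type in one sample) the
pipeline reports the mean vector length `|v|` (transcriptional
activity), the mean mutual distance `|u - v|` over all `choose(s, 2)`
pairs (activity plus stochasticity), and the mean mutual angle
(stochasticity alone; invariant to positive rescaling of each cell).

Numerical choices:

* The angle uses the standard cosine — the dot product over the
  *product* of norms — evaluated through the chord identity
  `2 * asin(|u/|u| - v/|v|| / 2)`. This keeps `theta(v, v) = 0` exactly
  and avoids the precision cliff of `acos` near parallel vectors. A sum
  of norms in the denominator (a form sometimes written down) is not an
  angle: it fails the identity case and is dimensionally inconsistent,
  so the package does not implement it.
* Groups with more than `max_pairs` pairs (default 500,000) use a
  seeded uniform subsample of pairs; the seed and pair count are
  recorded in the output.
* Singleton groups report a length but missing distance/angle; empty
  groups are skipped with a warning.

The Gaussian model is the calibration oracle. For `x ~ N(mu, Sigma)`
the differential entropy is `H = D/2 (1 + ln 2 pi) + 1/2 ln det Sigma`
and the root-mean-square pair distance is `sqrt(2 Tr Sigma)`, which by
Jensen's inequality upper-bounds the true mean distance; at D = 100 the
gap is under 0.3%, so the closed form validates the empirical statistic
to about a percent. Both quantities increase with the covariance scale,
which is why the empirical mean mutual distance serves as an
entropy-like noise measure. The pipeline always reports the empirical
mean, never the closed form.

# Cell-to-cell variability

Per tissue and sample, counts are normalized by library-size factors
(total UMI over the geometric mean of totals — a deliberate
simplification of pool-based deconvolution factors, which are a package
internal elsewhere and not defined by a formula we could adopt), log
transformed, and each gene's variance is decomposed against a
mean–variance trend: a running median over mean-ordered genes (window =
20% of genes, clipped at zero), with the biological component defined as
the residual. The decomposition conserves totals exactly and residuals
may be negative. Genes detected in fewer than 1% of a group's cells are
excluded by default.

Identifiability caveat: on the log scale, overdispersion is only
distinguishable from Poisson noise for genes with adequate counts. The
recovery tests therefore plant 10x-dispersion genes in a moderately
expressed regime (lognormal means around 5 UMI, 500 cells), where at
least 95 of 100 planted genes rank in the top 150 by biological
variance; at means near 0.5 UMI the same planting is largely invisible,
which is a property of the measurement scale, not a bug.

# Composition and cell cycle

Composition is per-sample cell-type fractions (summing to one within
sample); across conditions each type is tested with Welch's t-test (two
groups) or one-way ANOVA with Tukey HSD (three or more), on fractions,
matching how replicate-level proportions are usually compared.
Marker-positive fractions use a "> 0 normalized counts" positivity
threshold by default.

Cell-cycle scores follow the binned-control module-score scheme: genes
are ranked by mean expression and cut into 24 equal-frequency bins; for
each panel gene, up to 100 control genes are sampled (seeded) from its
bin; the score is mean panel expression minus mean control expression.
A cell is assigned S or G2M by the larger score when either is
positive, else G1. On zero-signal data both scores are exactly zero and
every cell is G1. Accuracy is assessed on cells carrying a planted
program: an unshifted (G1) cell's score is symmetric noise around zero,
so its phase call is a coin flip by construction — any threshold other
than zero would trade that off differently, and zero is the
conventional choice.

# Age-associated genes and reversal

Differential expression between two cell groups uses the Wilcoxon
rank-sum test per gene (tie-corrected normal approximation with
continuity correction) on normalized values, Bonferroni-adjusted over
tested genes. Genes enter testing when detected in at least 10% of
either group. The log2 fold change is computed on de-logged group means
with a pseudocount of 1:
`log2(mean(expm1 x_A) + 1) - log2(mean(expm1 x_B) + 1)` — the
first-named group is always the numerator, so swapping groups negates
every fold change. The pseudocount attenuates fold changes of lowly
expressed genes toward zero; at the default library scale a planted
2-fold effect on a median-expression gene is estimated around 0.85
rather than 1.0, which the recovery tests account for.

PAGs require `|log2FC| > 0.25` and adjusted `p < 0.05`, both strict
inequalities, with the sign of the old-vs-young change defining the
direction. A PAG is *reversed* when its old-vs-regenerated fold change
has the same sign as its old-vs-young fold change (old is the extreme
condition in both contrasts — regeneration restored youthful
expression). Two modes exist because published quadrant analyses are
ambiguous on this point: the default `strict` mode additionally
requires the regeneration contrast to pass the same significance
thresholds, while `sign_only` counts sign agreement alone. Neither is
asserted to be the original; the strict mode is the default because it
controls false reversals (under a planted reversal fraction of zero it
reports at most a few percent). Injury-response reversal is analogous
but restricted to PAGs that are themselves significant in the
6h-vs-0h contrast (shared genes form the denominator).

# The comparative-signature stage

Pseudo-bulk profiles are UMI sums per sample (or per sample x tissue).
Genes are optionally renamed through a strictly one-to-one ortholog map
(rows participating in any many-to-one relationship are dropped), then
filtered to those with at least 10 UMIs (inclusive) in at least 20% of
samples (inclusive, ceiling of the count). Size factors are
relative-log-expression (median-of-ratios): per sample, the median over
all-nonzero genes of the count divided by the gene's geometric mean.

The age model is per-gene OLS of `log(normalized expression + 1)` on
`log(age in months)`, fitted on young and old samples; regenerated
samples are excluded from the fit because their chronological age does
not reflect their biological state — which is precisely the hypothesis
under test. This ordinary least-squares fit replaces a count-model GLM
deliberately: the printed model formula is the contract, the GLM's
dispersion machinery is not, and parameter recovery (slope 1.0
recovered within 0.15 over 100 replicates at noise sigma = 0.1; null
genes significant at the nominal 5%) validates the substitution. The
ranking score is `-log10(p) * sgn(slope)` (log base 10 chosen as the
conventional reading of "log-transformed p-values"; zero when the slope
is zero), with ties broken by |slope| then gene id.

Preranked GSEA sorts genes by descending score and computes the
weighted Kolmogorov–Smirnov enrichment score (hit weight `|score|^1`).
The null is gene-label permutation — random same-size gene sets — not
sample permutation, because a preranked analysis has no sample labels
to permute; 5,000 permutations by default, shared across sets of equal
size. The p-value is the fraction of same-sign null ES at least as
extreme, floored at `1/(n_perm + 1)`; NES divides ES by the mean |null
ES| of the same sign; BH adjustment across sets with a 0.1 cutoff
downstream. The ES kernel agrees with an independent implementation to
numerical precision, null p-values are uniform by a KS check over 500
replicates, and negating all scores negates all ES (antisymmetry).

Signature PCA column-centers a gene x signature matrix of signed scores
(genes restricted to those present in every signature) and decomposes
it by SVD. Gene-level scores, rather than pathway-level NES, are the
default features; the choice is exposed to the caller, who can feed any
score matrix.

# Problem sizes and determinism

The shipped analysis and the test suite run at sizes chosen to make
every statistical claim testable on one CPU in minutes: the end-to-end
fixture is 2,000 genes x ~6,000 cells x 13 samples; recovery tests use
500 cells per condition (differential expression), 500 cells and 1,000
genes (variance decomposition), 12 pseudo-bulk samples x 100 replicates
(age model), and 500 replicates x 1,000 permutations (GSEA
calibration). All randomness descends from a single root seed through
deterministic stream splitting; a rerun with the same inputs, config
and seed reproduces every table byte for byte.

# Known limitations

* The Wilcoxon DE stage, like the tool it models, treats cells as
  independent replicates; sample-level pseudoreplication is not
  corrected (the pseudo-bulk stage exists partly for that reason).
* Library-size and RLE size factors replace pooled-deconvolution
  factors; at extreme sparsity they are less robust.
* The NB generator's dispersion is mean-independent; real UMI data show
  a dispersion trend.
* The reversal quadrant logic conditions on called PAGs; genes whose
  aging change is real but sub-threshold are invisible to it.
* `sqrt(2 Tr Sigma)` is used only as an oracle; on non-Gaussian data
  the empirical mean mutual distance has no closed-form reference.
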