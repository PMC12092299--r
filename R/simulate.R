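#' Design of a synthetic aging-and-regeneration experiment
#'
#' Defines a multi-sample, multi-tissue negative-binomial UMI simulation
#' with planted ground truth: per-tissue age-associated genes with fixed
#' |log2FC| and direction, a reversal fraction of those genes restored to
#' young expression in regenerated samples, condition-dependent cell-type
#' proportion shifts, planted cell-cycle programs, per-cell lognormal
#' library-size variation, mitochondrial genes recognised by id prefix,
#' and doublet-like high-UMI cells.
#'
#' The default design mirrors a head-sampling study across the life course
#' of a regenerative animal: 13 biological samples — six young (5 or 7
#' months), four old (12-32 months) and three regenerated (32 months
#' chronological age, three amputation-regeneration rounds) — over four
#' tissues, with ages counted in months since fertilization.
#'
#' @param n_genes number of genes.
#' @param cell_types character vector of tissue/cell-type labels.
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (young/old/regenerated) and `age_months` (> 0).
#' @param cells_per_sample_per_type baseline cell count per sample x type.
#' @param baseline_mean median NB mean per gene (before per-gene lognormal
#'   heterogeneity with `gene_sdlog`).
#' @param gene_sdlog sdlog of per-gene baseline-mean heterogeneity.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2),
#'   shared across cells; 0 gives Poisson noise.
#' @param pag_spec named list per tissue: `list(n_up, n_down,
#'   effect_log2fc)` with `effect_log2fc > 0`.
#' @param reversal_fraction fraction of planted PAGs whose regenerated mean
#'   is restored to the young level (the rest retain the old level).
#' @param proportion_shift named list per condition of named per-type
#'   multipliers on `cells_per_sample_per_type` (defaults to all 1).
#' @param mito_gene_fraction fraction of genes given the mitochondrial id
#'   prefix.
#' @param mito_prefix mitochondrial gene-id prefix.
#' @param n_highmito_cells total cells planted with inflated mitochondrial
#'   expression (spread across samples).
#' @param highmito_level target expected mito fraction of planted cells.
#' @param doublet_fraction fraction of cells given doubled library size
#'   (doublet-like high-UMI outliers).
#' @param libsize_sdlog sdlog of the per-cell lognormal library-size
#'   multiplier.
#' @param marker_genes_per_type genes per cell type given elevated
#'   expression in that type (crude cell identity).
#' @param marker_fold mean multiplier of a type's marker genes in that type.
#' @param n_cc_genes genes per cell-cycle panel (S and G2M).
#' @param cc_effect_log2 additive log2 shift of panel means in cells of the
#'   matching phase.
#' @param phase_probs probabilities of G1/S/G2M per cell.
#' @param seed root seed; every sub-generator derives its own stream.
#' @return a validated `simulation_design` list.
#' @export
simulation_design <- function(
    n_genes = 2000L,
    cell_types = c("neoblast", "neural", "muscle", "intestine"),
    samples = default_samples(),
    cells_per_sample_per_type = 115L,
    baseline_mean = 0.5,
    gene_sdlog = 1,
    nb_dispersion = 0.4,
    pag_spec = NULL,
    reversal_fraction = 0.7,
    proportion_shift = NULL,
    mito_gene_fraction = 0.02,
    mito_prefix = "MT-",
    n_highmito_cells = 0L,
    highmito_level = 0.5,
    doublet_fraction = 0.01,
    libsize_sdlog = 0.3,
    marker_genes_per_type = 25L,
    marker_fold = 4,
    n_cc_genes = 20L,
    cc_effect_log2 = 2,
    phase_probs = c(G1 = 0.6, S = 0.2, G2M = 0.2),
    seed = 1L) {
  if (is.null(pag_spec))
    pag_spec <- stats::setNames(
      rep(list(list(n_up = 40L, n_down = 40L, effect_log2fc = 1)),
          length(cell_types)), cell_types)
  if (is.null(proportion_shift))
    proportion_shift <- list()
  design <- list(
    n_genes = as.integer(n_genes), cell_types = cell_types,
    samples = samples,
    cells_per_sample_per_type = as.integer(cells_per_sample_per_type),
    baseline_mean = baseline_mean, gene_sdlog = gene_sdlog,
    nb_dispersion = nb_dispersion, pag_spec = pag_spec,
    reversal_fraction = reversal_fraction,
    proportion_shift = proportion_shift,
    mito_gene_fraction = mito_gene_fraction, mito_prefix = mito_prefix,
    n_highmito_cells = as.integer(n_highmito_cells),
    highmito_level = highmito_level,
    doublet_fraction = doublet_fraction, libsize_sdlog = libsize_sdlog,
    marker_genes_per_type = as.integer(marker_genes_per_type),
    marker_fold = marker_fold, n_cc_genes = as.integer(n_cc_genes),
    cc_effect_log2 = cc_effect_log2, phase_probs = phase_probs,
    seed = as.integer(seed))
  validate_design(design)
  structure(design, class = c("simulation_design", "list"))
}

#' @rdname simulation_design
#' @export
default_samples <- function() {
  data.frame(
    sample_id = c(paste0("young_", 1:6), paste0("old_", 1:4),
                  paste0("regen_", 1:3)),
    condition = c(rep("young", 6), rep("old", 4), rep("regenerated", 3)),
    age_months = c(5, 5, 5, 5, 7, 7, 12, 18, 18, 32, 32, 32, 32),
    stringsAsFactors = FALSE)
}

validate_design <- function(d) {
  assert_that(d$n_genes > 0, "n_genes must be positive")
  assert_that(length(d$cell_types) > 0, "need at least one cell type")
  assert_that(d$cells_per_sample_per_type > 0, "zero cells requested")
  assert_that(all(c("sample_id", "condition", "age_months") %in%
                    names(d$samples)), "samples needs sample_id/condition/age_months")
  assert_that(all(d$samples$condition %in% c("young", "old", "regenerated")),
              "condition must be young/old/regenerated")
  assert_that(all(d$samples$age_months > 0),
              "sample ages must be strictly positive (time since fertilization)")
  assert_that(d$reversal_fraction >= 0 && d$reversal_fraction <= 1,
              "reversal_fraction must lie in [0, 1]")
  assert_that(d$baseline_mean > 0 && d$nb_dispersion >= 0,
              "baseline_mean must be > 0 and nb_dispersion >= 0")
  assert_that(d$mito_gene_fraction >= 0 && d$mito_gene_fraction < 1,
              "mito_gene_fraction must lie in [0, 1)")
  for (ct in names(d$pag_spec)) {
    ps <- d$pag_spec[[ct]]
    assert_that(ps$effect_log2fc >= 0, "effect sizes must be >= 0")
    assert_that(ps$n_up >= 0 && ps$n_down >= 0, "PAG counts must be >= 0")
  }
  invisible(d)
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate an annotated count matrix with planted ground truth
#'
#' Draws UMI counts gene-by-cell from a negative binomial whose mean is the
#' product of a per-gene baseline, cell-type marker modulation, the
#' condition-dependent planted age effect (old samples scale planted PAGs
#' by `2^(+-effect_log2fc)`; regenerated samples restore a
#' `reversal_fraction` of them to the young mean and keep the rest at the
#' old mean), the planted cell-cycle program, and a per-cell lognormal
#' library-size factor. Fully reproducible from `design$seed`.
#'
#' @param design a [simulation_design()].
#' @return list with `counts` (an [annotated_counts()]) and `truth`, a
#'   `ground_truth` list: `pag_ids_by_tissue` (up/down/reversed gene ids),
#'   `true_proportions`, `true_phase`, `highmito_cells`, `doublet_cells`,
#'   `s_genes`, `g2m_genes`, `marker_genes`, `base_means`.
#' @export
simulate_counts <- function(design) {
  validate_design(design)
  d <- design
  n_mito <- round(d$mito_gene_fraction * d$n_genes)
  gene_ids <- c(if (n_mito > 0) paste0(d$mito_prefix, seq_len(n_mito)),
                sprintf("g%04d", seq_len(d$n_genes - n_mito)))
  plain <- gene_ids[!startsWith(gene_ids, d$mito_prefix)]

  base_means <- with_seed(child_seed(d$seed, 1),
    stats::rlnorm(d$n_genes, meanlog = log(d$baseline_mean), sdlog = d$gene_sdlog))
  names(base_means) <- gene_ids

  # cell-cycle panels and per-type markers are drawn from non-mito genes
  pool <- plain
  cc <- with_seed(child_seed(d$seed, 2), {
    s_genes <- sample(pool, d$n_cc_genes)
    g2m_genes <- sample(setdiff(pool, s_genes), d$n_cc_genes)
    list(s = s_genes, g2m = g2m_genes)
  })
  pool <- setdiff(pool, c(cc$s, cc$g2m))
  markers <- with_seed(child_seed(d$seed, 3), {
    out <- list(); avail <- pool
    for (ct in d$cell_types) {
      out[[ct]] <- sample(avail, min(d$marker_genes_per_type, length(avail)))
      avail <- setdiff(avail, out[[ct]])
    }
    out
  })

  # planted PAGs per tissue, with a reversed subset; effects are planted on
  # genes at or above the median baseline so the fold change is expressed
  # on genes a DE analysis can actually detect
  pags <- with_seed(child_seed(d$seed, 4), {
    out <- list(); avail <- setdiff(pool, unlist(markers))
    eligible_floor <- stats::median(base_means[avail])
    avail <- avail[base_means[avail] >= eligible_floor]
    for (ct in names(d$pag_spec)) {
      ps <- d$pag_spec[[ct]]
      assert_that(length(avail) >= ps$n_up + ps$n_down,
                  paste0("not enough eligible genes to plant PAGs for '", ct,
                         "'; increase n_genes or reduce pag_spec counts"))
      up <- sample(avail, ps$n_up); avail <- setdiff(avail, up)
      down <- sample(avail, ps$n_down); avail <- setdiff(avail, down)
      all_pags <- c(up, down)
      n_rev <- round(d$reversal_fraction * length(all_pags))
      reversed <- if (n_rev > 0) sample(all_pags, n_rev) else character()
      out[[ct]] <- list(up = up, down = down, reversed = reversed,
                        effect_log2fc = ps$effect_log2fc)
    }
    out
  })

  # per-(sample, type) cell counts after proportion shifts
  counts_per <- matrix(d$cells_per_sample_per_type,
                       nrow = nrow(d$samples), ncol = length(d$cell_types),
                       dimnames = list(d$samples$sample_id, d$cell_types))
  for (cond in names(d$proportion_shift)) {
    mult <- d$proportion_shift[[cond]]
    rows <- d$samples$condition == cond
    for (ct in names(mult))
      counts_per[rows, ct] <- round(counts_per[rows, ct] * mult[[ct]])
  }
  assert_that(all(counts_per >= 1), "proportion shifts produced empty groups")

  n_cells_total <- sum(counts_per)
  blocks <- list(); meta <- list(); phases <- list()
  cell_counter <- 0L
  for (si in seq_len(nrow(d$samples))) {
    smp <- d$samples$sample_id[si]
    cond <- d$samples$condition[si]
    block_seed <- child_seed(d$seed, 100 + si)
    res <- with_seed(block_seed, {
      mats <- list(); metas <- list(); phs <- list()
      for (ct in d$cell_types) {
        nc <- counts_per[smp, ct]
        mu <- base_means
        mu[markers[[ct]]] <- mu[markers[[ct]]] * d$marker_fold
        pg <- pags[[ct]]
        if (!is.null(pg)) {
          up_f <- 2^pg$effect_log2fc; dn_f <- 2^(-pg$effect_log2fc)
          if (cond == "old") {
            mu[pg$up] <- mu[pg$up] * up_f
            mu[pg$down] <- mu[pg$down] * dn_f
          } else if (cond == "regenerated") {
            keep_old_up <- setdiff(pg$up, pg$reversed)
            keep_old_dn <- setdiff(pg$down, pg$reversed)
            mu[keep_old_up] <- mu[keep_old_up] * up_f
            mu[keep_old_dn] <- mu[keep_old_dn] * dn_f
          }
        }
        phase <- sample(names(d$phase_probs), nc, replace = TRUE,
                        prob = d$phase_probs)
        lib <- stats::rlnorm(nc, meanlog = -d$libsize_sdlog^2 / 2,
                             sdlog = d$libsize_sdlog)
        mumat <- outer(mu, lib)
        cc_f <- 2^d$cc_effect_log2
        if (any(phase == "S"))
          mumat[cc$s, phase == "S"] <- mumat[cc$s, phase == "S"] * cc_f
        if (any(phase == "G2M"))
          mumat[cc$g2m, phase == "G2M"] <- mumat[cc$g2m, phase == "G2M"] * cc_f
        m <- matrix(rnb(length(mumat), mumat, d$nb_dispersion),
                    nrow = d$n_genes)
        rownames(m) <- gene_ids
        mats[[ct]] <- m
        metas[[ct]] <- data.frame(
          sample_id = smp, age_months = d$samples$age_months[si],
          condition = cond, tissue = ct, stringsAsFactors = FALSE)
        phs[[ct]] <- phase
      }
      list(mats = mats, metas = metas, phs = phs)
    })
    for (ct in d$cell_types) {
      nc <- ncol(res$mats[[ct]])
      ids <- sprintf("%s_c%05d", smp, cell_counter + seq_len(nc))
      cell_counter <- cell_counter + nc
      colnames(res$mats[[ct]]) <- ids
      mt <- res$metas[[ct]][rep(1, nc), , drop = FALSE]
      mt$cell_id <- ids
      blocks[[length(blocks) + 1L]] <- res$mats[[ct]]
      meta[[length(meta) + 1L]] <- mt
      phases[[length(phases) + 1L]] <-
        stats::setNames(res$phs[[ct]], ids)
    }
  }
  mat <- do.call(cbind, blocks)
  meta <- do.call(rbind, meta)
  rownames(meta) <- meta$cell_id
  true_phase <- do.call(c, phases)

  # doublet-like high-UMI cells: add a second, scale-matched draw so the
  # planted cell's expected total doubles
  doublets <- character()
  if (d$doublet_fraction > 0) {
    doublets <- with_seed(child_seed(d$seed, 5), {
      picked <- sample(colnames(mat),
                       max(0L, round(d$doublet_fraction * ncol(mat))))
      total_base <- sum(base_means)
      for (cid in picked) {
        scale_c <- sum(mat[, cid]) / total_base
        mat[, cid] <- mat[, cid] +
          rnb(d$n_genes, base_means * scale_c, d$nb_dispersion)
      }
      picked
    })
  }

  # planted high-mito cells: inflate mito counts toward a target fraction
  highmito <- character()
  if (d$n_highmito_cells > 0 && n_mito > 0) {
    mito_rows <- startsWith(gene_ids, d$mito_prefix)
    highmito <- with_seed(child_seed(d$seed, 6), {
      picked <- sample(setdiff(colnames(mat), doublets), d$n_highmito_cells)
      M <- sum(base_means[mito_rows]); Tot <- sum(base_means)
      f <- d$highmito_level * (Tot - M) / ((1 - d$highmito_level) * M)
      for (cid in picked)
        mat[mito_rows, cid] <- rnb(n_mito, base_means[mito_rows] * f,
                                   d$nb_dispersion)
      picked
    })
  }

  # drop cells that ended with zero totals (possible at very low means)
  nonzero <- colSums(mat) > 0
  mat <- mat[, nonzero, drop = FALSE]
  meta <- meta[nonzero, , drop = FALSE]
  true_phase <- true_phase[colnames(mat)]

  ac <- annotated_counts(mat, meta, mito_prefix = d$mito_prefix)
  prop <- counts_per / rowSums(counts_per)
  truth <- list(
    pag_ids_by_tissue = pags,
    true_proportions = prop,
    true_phase = as.list(true_phase),
    highmito_cells = highmito,
    doublet_cells = doublets,
    s_genes = cc$s, g2m_genes = cc$g2m,
    marker_genes = markers,
    base_means = as.list(base_means))
  list(counts = ac, truth = truth)
}

#' Draw cells from a multivariate Gaussian latent model
#'
#' i.i.d. draws from `N(mu, Sigma)`; the latent model used to calibrate the
#' mean-mutual-distance statistic against its closed forms.
#'
#' @param mu mean vector (length D).
#' @param sigma D x D symmetric PSD covariance matrix (a zero matrix gives
#'   identical cells at `mu`).
#' @param n_cells number of cells.
#' @param seed RNG seed.
#' @return D x n_cells matrix (features in rows, cells in columns).
#' @export
simulate_gaussian_cells <- function(mu, sigma, n_cells, seed = 1L) {
  sigma <- as.matrix(sigma)
  D <- length(mu)
  assert_that(nrow(sigma) == D && ncol(sigma) == D,
              "mean and covariance dimensions differ")
  assert_that(isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8)),
              "covariance must be symmetric")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  assert_that(min(ev) > -1e-8 * max(abs(ev), 1),
              "covariance is not positive semi-definite")
  assert_that(n_cells >= 1, "n_cells must be >= 1")
  X <- with_seed(seed, MASS::mvrnorm(n_cells, mu = mu, Sigma = sigma))
  if (n_cells == 1L) X <- matrix(X, nrow = 1)
  out <- t(X)
  rownames(out) <- paste0("f", seq_len(D))
  colnames(out) <- paste0("cell", seq_len(n_cells))
  out
}

#' Simulate gene-set collections for enrichment testing
#'
#' Builds fixture gene sets over a universe `r0001 ... r<ranking_size>`
#' interpreted as a ranking (position 1 = top). One optional planted set is
#' drawn from the top `planted_top` positions; all remaining sets are drawn
#' uniformly from the whole universe.
#'
#' @param ranking_size universe size.
#' @param n_sets number of sets.
#' @param set_size genes per set (>= 5, <= `ranking_size`).
#' @param planted_top if > 0, the first set (named `"planted_top"`) is
#'   sampled from the top `planted_top` ranking positions.
#' @param seed RNG seed.
#' @return named list of character vectors (a gene-set collection).
#' @export
simulate_genesets <- function(ranking_size, n_sets, set_size = 20L,
                              planted_top = 0L, seed = 1L) {
  assert_that(set_size >= 5, "set sizes must be >= 5")
  assert_that(set_size <= ranking_size, "set larger than universe")
  universe <- sprintf("r%04d", seq_len(ranking_size))
  with_seed(seed, {
    sets <- list()
    if (planted_top > 0) {
      assert_that(planted_top >= set_size, "planted_top must be >= set_size")
      sets[["planted_top"]] <- sample(universe[seq_len(planted_top)], set_size)
    }
    n_random <- n_sets - length(sets)
    for (i in seq_len(max(0L, n_random)))
      sets[[sprintf("random_%03d", i)]] <- sample(universe, set_size)
    sets
  })
}
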