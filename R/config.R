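#' Default run configuration
#'
#' Central registry of every tunable threshold in the pipeline. Defaults
#' reproduce the study's stated analysis settings: cells need at least 500
#' detected genes; the 2,000 highest-SD genes form the HVG panel;
#' age-associated genes require |log2FC| > 0.25 at adjusted p < 0.05;
#' pseudo-bulk genes need >= 10 UMIs in >= 20% of samples; GSEA runs 5,000
#' permutations with an adjusted-p cutoff of 0.1.
#'
#' @return nested named list of defaults.
#' @keywords internal
default_config <- function() {
  list(
    seed = 1L,
    qc = list(
      min_genes_per_cell = 500L,   # cells below this are removed
      max_mito_fraction  = 0.2,    # "high mito" removal threshold
      high_umi_mad_k     = 5,      # doublet-like flag: median + k * MAD
      remove_high_umi    = FALSE   # flag only, unless asked to drop
    ),
    normalization = list(
      scale_factor = 1e4           # per-cell target before log1p
    ),
    hvg = list(
      n_hvg = 2000L,
      on_log = TRUE                # SD computed on log-normalized values
    ),
    de = list(
      log2fc_min  = 0.25,
      adj_p_max   = 0.05,
      min_pct     = 0.1,
      pseudocount = 1
    ),
    bulk_de = list(
      log2fc_min = 1,
      adj_p_max  = 0.05
    ),
    reversal = list(
      mode = "strict"              # "strict" or "sign_only"
    ),
    entropy = list(
      max_pairs = 500000L
    ),
    variability = list(
      trend_window_frac = 0.2,
      min_detect_frac   = 0.01
    ),
    cellcycle = list(
      n_bins = 24L,
      n_ctrl = 100L
    ),
    pseudobulk = list(
      min_umi             = 10,
      min_sample_fraction = 0.2,
      pseudocount         = 1
    ),
    gsea = list(
      n_permutations = 5000L,
      adj_p_cutoff   = 0.1,
      weight         = 1
    ),
    mito_prefix = "MT-"
  )
}

merge_config <- function(defaults, overrides, path = "") {
  for (key in names(overrides)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: '", full, "'", call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(overrides[[key]]))
        stop("configuration key '", full, "' must be a named list", call. = FALSE)
      defaults[[key]] <- merge_config(defaults[[key]], overrides[[key]], full)
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

#' Build a run configuration
#'
#' Starts from [default_config()] values and applies overrides given either
#' as a nested list or as `section = list(key = value)` arguments. Any key
#' not present in the defaults is an error, which guards against silently
#' misspelled thresholds.
#'
#' @param ... nested overrides, e.g. `qc = list(max_mito_fraction = 0.1)`.
#' @param overrides optional single nested list (e.g. parsed from YAML).
#' @return a validated `screjuv_config` list.
#' @examples
#' cfg <- run_config(hvg = list(n_hvg = 500))
#' cfg$hvg$n_hvg
#' @export
run_config <- function(..., overrides = NULL) {
  cfg <- default_config()
  dots <- list(...)
  if (length(dots)) cfg <- merge_config(cfg, dots)
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
  structure(cfg, class = c("screjuv_config", "list"))
}

validate_config <- function(cfg) {
  assert_that(cfg$qc$min_genes_per_cell >= 0, "min_genes_per_cell must be >= 0")
  assert_that(cfg$qc$max_mito_fraction >= 0 && cfg$qc$max_mito_fraction <= 1,
              "max_mito_fraction must lie in [0, 1]")
  assert_that(cfg$normalization$scale_factor > 0, "scale_factor must be positive")
  assert_that(cfg$hvg$n_hvg >= 1, "n_hvg must be >= 1")
  assert_that(cfg$de$log2fc_min >= 0, "log2fc_min must be >= 0")
  assert_that(cfg$de$adj_p_max > 0 && cfg$de$adj_p_max <= 1,
              "adj_p_max must lie in (0, 1]")
  assert_that(cfg$pseudobulk$min_sample_fraction >= 0 &&
                cfg$pseudobulk$min_sample_fraction <= 1,
              "min_sample_fraction must lie in [0, 1]")
  assert_that(cfg$gsea$n_permutations >= 1, "n_permutations must be >= 1")
  assert_that(cfg$reversal$mode %in% c("strict", "sign_only"),
              "reversal mode must be 'strict' or 'sign_only'")
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [default_config()].
#' @return a `screjuv_config` list.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), paste0("config file not found: ", path))
  run_config(overrides = yaml::read_yaml(path))
}

#' @export
print.screjuv_config <- function(x, ...) {
  cat("<screjuv_config>\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
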