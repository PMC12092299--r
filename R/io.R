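#' Annotated count matrix
#'
#' The pipeline's central object: a sparse gene x cell UMI matrix with
#' per-cell metadata. Metadata must carry `sample_id`, `age_months`,
#' `condition` (one of young/old/regenerated) and `tissue`; QC metric
#' columns (`n_genes_detected`, `total_umi`, `mito_fraction`) are computed
#' on construction when absent. Mitochondrial genes are recognised by an
#' identifier prefix (default `"MT-"`).
#'
#' @param counts gene x cell matrix of non-negative integers (dense or
#'   sparse); coerced to `dgCMatrix`. Row and column names are the gene and
#'   cell identifiers.
#' @param cell_meta data.frame keyed by `cell_id` (or with rownames equal to
#'   the cell identifiers).
#' @param mito_prefix gene-id prefix marking mitochondrial genes.
#' @return an `annotated_counts` object (list with `matrix`, `gene_ids`,
#'   `cell_ids`, `cell_meta`).
#' @export
annotated_counts <- function(counts, cell_meta, mito_prefix = "MT-") {
  counts <- as_csparse(counts)
  assert_that(!is.null(rownames(counts)) && !is.null(colnames(counts)),
              "counts must have gene rownames and cell colnames")
  assert_that(!anyDuplicated(rownames(counts)), "duplicate gene identifiers")
  assert_that(!anyDuplicated(colnames(counts)), "duplicate cell identifiers")
  x <- counts@x
  assert_that(all(x >= 0), "counts must be non-negative")
  assert_that(all(x == round(x)), "counts must be integers")

  if (!is.null(cell_meta$cell_id)) {
    rownames(cell_meta) <- cell_meta$cell_id
  }
  missing <- setdiff(colnames(counts), rownames(cell_meta))
  if (length(missing))
    stop("cell metadata missing for barcode(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "", call. = FALSE)
  cell_meta <- cell_meta[colnames(counts), , drop = FALSE]
  cell_meta$cell_id <- colnames(counts)

  for (col in c("sample_id", "condition", "tissue"))
    assert_that(col %in% names(cell_meta),
                paste0("cell_meta must contain column '", col, "'"))
  assert_that(all(cell_meta$condition %in% c("young", "old", "regenerated")),
              "condition must be one of young/old/regenerated")
  if ("age_months" %in% names(cell_meta))
    assert_that(all(cell_meta$age_months > 0), "ages must be positive")

  if (is.null(cell_meta$total_umi))
    cell_meta$total_umi <- Matrix::colSums(counts)
  if (is.null(cell_meta$n_genes_detected))
    cell_meta$n_genes_detected <- Matrix::colSums(counts > 0)
  if (is.null(cell_meta$mito_fraction)) {
    mito <- startsWith(rownames(counts), mito_prefix)
    mito_umi <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else 0
    cell_meta$mito_fraction <- ifelse(cell_meta$total_umi > 0,
                                      mito_umi / cell_meta$total_umi, 0)
  }
  assert_that(all(cell_meta$mito_fraction >= 0 & cell_meta$mito_fraction <= 1),
              "mito_fraction must lie in [0, 1]")

  structure(
    list(matrix = counts, gene_ids = rownames(counts),
         cell_ids = colnames(counts), cell_meta = cell_meta),
    class = "annotated_counts"
  )
}

#' @export
print.annotated_counts <- function(x, ...) {
  cat(sprintf("<annotated_counts> %d genes x %d cells\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("samples:", paste(unique(x$cell_meta$sample_id), collapse = ", "), "\n")
  cat("conditions:", paste(sort(unique(x$cell_meta$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.annotated_counts <- function(x) dim(x$matrix)

#' Subset an annotated count matrix by cells (and optionally genes)
#'
#' @param x an `annotated_counts`.
#' @param cells cell identifiers or logical/integer index over columns.
#' @param genes optional gene identifiers or index over rows.
#' @return an `annotated_counts` restricted to the selection; QC metrics are
#'   carried over unchanged (they describe the original cells).
#' @export
subset_cells <- function(x, cells, genes = NULL) {
  stopifnot(inherits(x, "annotated_counts"))
  m <- x$matrix[, cells, drop = FALSE]
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  meta <- x$cell_meta[colnames(m), , drop = FALSE]
  structure(list(matrix = m, gene_ids = rownames(m),
                 cell_ids = colnames(m), cell_meta = meta),
            class = "annotated_counts")
}

#' Write an annotated count matrix to a directory
#'
#' Emits the conventional sparse-matrix triplet layout: `matrix.mtx`
#' (Matrix Market, 1-based indices on disk), `genes.tsv`, `barcodes.tsv`,
#' plus `cell_meta.csv`.
#'
#' @param x an `annotated_counts`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "annotated_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$matrix, file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  utils::write.csv(x$cell_meta, file.path(dir, "cell_meta.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read an annotated count matrix
#'
#' Accepts either a directory in the `matrix.mtx` + `genes.tsv` +
#' `barcodes.tsv` + `cell_meta.csv` layout written by [write_counts()], or a
#' dense TSV (genes in rows, cells in columns) plus a metadata CSV.
#'
#' @param dir_or_tsv directory path, or path to a dense TSV count table.
#' @param meta_csv metadata CSV (required for the TSV form; defaults to
#'   `cell_meta.csv` inside a directory).
#' @param mito_prefix passed to [annotated_counts()].
#' @return an `annotated_counts`.
#' @export
read_counts <- function(dir_or_tsv, meta_csv = NULL, mito_prefix = "MT-") {
  if (dir.exists(dir_or_tsv)) {
    dir <- dir_or_tsv
    m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
    genes <- readLines(file.path(dir, "genes.tsv"))
    cells <- readLines(file.path(dir, "barcodes.tsv"))
    assert_that(nrow(m) == length(genes) && ncol(m) == length(cells),
                "matrix dimensions do not match genes.tsv/barcodes.tsv")
    dimnames(m) <- list(genes, cells)
    meta <- utils::read.csv(meta_csv %||% file.path(dir, "cell_meta.csv"),
                            stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(dir_or_tsv, row.names = 1, check.names = FALSE)
    m <- as.matrix(tab)
    assert_that(!is.null(meta_csv), "meta_csv is required for dense TSV input")
    meta <- utils::read.csv(meta_csv, stringsAsFactors = FALSE)
  }
  annotated_counts(m, meta, mito_prefix = mito_prefix)
}

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. Member
#' lists are deduplicated; empty sets are skipped with a warning; a set name
#' appearing twice keeps its first occurrence.
#'
#' @param path GMT file.
#' @return named list of character vectors, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    name <- parts[1]
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning("skipping empty gene set '", name, "'", call. = FALSE)
      next
    }
    if (name %in% names(sets)) {
      warning("duplicate gene set '", name, "'; keeping first", call. = FALSE)
      next
    }
    sets[[name]] <- members
    descs[name] <- if (length(parts) >= 2) parts[2] else ""
  }
  attr(sets, "description") <- descs
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional named descriptions (default `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    desc <- descriptions[[nm]] %||% "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column ortholog map, keeping one-to-one pairs only
#'
#' Rows participating in any many-to-one or one-to-many relationship are
#' dropped (on either side), with a message reporting how many.
#'
#' @param path TSV with two columns: source gene id, target gene id. A
#'   header line is detected and skipped if the first row repeats in neither
#'   column.
#' @param header logical; whether the file has a header row.
#' @return named character vector: `map[source_id] == target_id`.
#' @export
read_ortholog_map <- function(path, header = FALSE) {
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  assert_that(ncol(tab) >= 2, "ortholog map must have two columns")
  src <- as.character(tab[[1]]); dst <- as.character(tab[[2]])
  keep <- !(src %in% src[duplicated(src)]) & !(dst %in% dst[duplicated(dst)])
  dropped <- sum(!keep)
  if (dropped > 0)
    message(dropped, " ortholog rows dropped (not one-to-one)")
  stats::setNames(dst[keep], src[keep])
}

#' Serialize simulation ground truth to JSON
#'
#' @param truth a `ground_truth` list from [simulate_counts()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
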