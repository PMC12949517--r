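#' Build a validated gene-by-cell count matrix
#'
#' Expression matrices throughout the package are sparse `dgCMatrix` objects
#' with genes as rows and cells as columns, carrying gene symbols and cell
#' identifiers as dimnames. This constructor validates the invariants:
#' finite non-negative counts, no duplicated gene symbols or cell ids, and
#' dimensions matching the identifier lists.
#'
#' @param counts matrix-like of non-negative integer counts (genes x cells).
#' @param genes character vector of gene symbols (defaults to rownames).
#' @param cells character vector of cell identifiers (defaults to colnames).
#' @return a `dgCMatrix` with dimnames set.
#' @export
expression_matrix <- function(counts, genes = rownames(counts), cells = colnames(counts)) {
  m <- Matrix::Matrix(counts, sparse = TRUE)
  if (methods::is(m, "nMatrix")) m <- methods::as(m, "dMatrix")  # pattern-only mtx
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  if (is.null(genes) || is.null(cells)) {
    abort_validation("gene symbols and cell ids are required")
  }
  if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
    abort_integrity("identifier lengths (%d genes, %d cells) do not match matrix dimensions %d x %d",
                    length(genes), length(cells), nrow(m), ncol(m))
  }
  if (anyDuplicated(genes)) abort_validation("duplicate gene symbols")
  if (anyDuplicated(cells)) abort_validation("duplicate cell ids")
  if (length(m@x) && (any(!is.finite(m@x)) || any(m@x < 0))) {
    abort_validation("counts must be finite and >= 0")
  }
  dimnames(m) <- list(as.character(genes), as.character(cells))
  m
}

#' Read a MatrixMarket count triple
#'
#' Reads the CellRanger-style interchange triple `matrix.mtx` (coordinate
#' MatrixMarket, genes as rows), `features.tsv` (1-3 tab-separated columns,
#' first column used as the gene symbol) and `barcodes.tsv` from a directory.
#'
#' @param dir directory containing the three files.
#' @return a sparse gene-by-cell count matrix (`dgCMatrix`) with dimnames.
#' @export
read_counts_triple <- function(dir) {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  for (p in paths) {
    if (!file.exists(p)) abort_format("missing file: %s", p)
  }
  m <- Matrix::readMM(paths[1])
  feats <- utils::read.table(paths[2], sep = "\t", header = FALSE,
                             colClasses = "character", quote = "")
  bars <- utils::read.table(paths[3], sep = "\t", header = FALSE,
                            colClasses = "character", quote = "")
  if (nrow(feats) != nrow(m)) {
    abort_integrity("matrix.mtx declares %d genes but features.tsv lists %d", nrow(m), nrow(feats))
  }
  if (nrow(bars) != ncol(m)) {
    abort_integrity("matrix.mtx declares %d cells but barcodes.tsv lists %d", ncol(m), nrow(bars))
  }
  expression_matrix(m, genes = feats[[1]], cells = bars[[1]])
}

#' Write a MatrixMarket count triple
#'
#' Inverse of [read_counts_triple()]; integer counts round-trip exactly.
#' A sidecar `meta.json` records matrix dimensions and provenance metadata.
#'
#' @param m gene-by-cell count matrix with dimnames.
#' @param dir output directory (created if needed).
#' @param meta optional named list merged into the sidecar JSON.
#' @return `dir`, invisibly.
#' @export
write_counts_triple <- function(m, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "features.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  meta <- c(list(n_genes = nrow(m), n_cells = ncol(m), format = "MatrixMarket coordinate"), meta)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Log-normalize counts to log1p counts-per-10k
#'
#' Each cell's counts are scaled to `scale_factor` total and transformed with
#' the natural `log1p`: `value = ln(1 + count / total * scale_factor)`.
#' Cells with zero total counts are kept as all-zero columns and flagged in
#' the `zero_total_cells` attribute rather than silently dropped.
#'
#' @param m gene-by-cell count matrix.
#' @param scale_factor library-size scaling target (default 1e4).
#' @return sparse normalized matrix with attributes `scale_factor` and
#'   `zero_total_cells`.
#' @export
normalize_log_cp10k <- function(m, scale_factor = 1e4) {
  m <- methods::as(m, "CsparseMatrix")
  if (length(m@x) && any(m@x < 0)) abort_validation("counts must be >= 0")
  totals <- Matrix::colSums(m)
  inv <- ifelse(totals > 0, scale_factor / totals, 0)
  nm <- m %*% Matrix::Diagonal(x = inv)
  nm <- methods::as(nm, "CsparseMatrix")
  nm@x <- log1p(nm@x)
  dimnames(nm) <- dimnames(m)
  attr(nm, "scale_factor") <- scale_factor
  attr(nm, "zero_total_cells") <- colnames(m)[totals == 0]
  nm
}

#' Select highly variable genes
#'
#' Genes are ranked by descending variance of log-normalized expression
#' across cells, with a deterministic lexicographic tie-break on the gene
#' symbol. No randomness is involved.
#'
#' @param nm normalized gene-by-cell matrix.
#' @param n_genes number of genes to return.
#' @return character vector of gene symbols, most variable first.
#' @export
select_hvgs <- function(nm, n_genes) {
  if (n_genes <= 0) abort_validation("n_genes must be > 0")
  if (n_genes > nrow(nm)) abort_validation("n_genes (%d) exceeds gene count (%d)", n_genes, nrow(nm))
  v <- row_vars(nm)
  ord <- order(-v, rownames(nm), method = "radix")
  rownames(nm)[ord][seq_len(n_genes)]
}

#' Read / write per-cell metadata tables
#'
#' Cell tables are tibbles with the fixed column set `cell_id`, `species`,
#' `modality`, `section_id`, `x_um`, `y_um`, `axis_mm`, `subregion`,
#' `cell_type`, `depth_frac`. Spatial cells carry section, planar (micron)
#' and longitudinal (mm) coordinates; reference cells carry NA there.
#'
#' @param path CSV path.
#' @return a tibble (for the reader); `path` invisibly (for the writer).
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) abort_format("missing file: %s", path)
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           cell_id = "c", species = "c", modality = "c",
                           section_id = "c", x_um = "d", y_um = "d",
                           axis_mm = "d", subregion = "c", cell_type = "c",
                           depth_frac = "d"))
  validate_cell_table(tbl)
  tbl
}

#' @rdname read_cell_table
#' @param cells cell table tibble.
#' @export
write_cell_table <- function(cells, path) {
  validate_cell_table(cells)
  readr::write_csv(cells, path)
  invisible(path)
}

cell_table_columns <- c("cell_id", "species", "modality", "section_id", "x_um",
                        "y_um", "axis_mm", "subregion", "cell_type", "depth_frac")

validate_cell_table <- function(cells) {
  missing <- setdiff(cell_table_columns, names(cells))
  if (length(missing)) abort_validation("cell table missing columns: %s", paste(missing, collapse = ", "))
  sp <- cells$modality == "spatial"
  bad <- sp & (is.na(cells$section_id) | is.na(cells$x_um) | is.na(cells$y_um) | is.na(cells$axis_mm))
  if (any(bad)) abort_validation("%d spatial cells lack section/coordinate fields", sum(bad))
  ax <- dplyr::distinct(cells[sp, c("section_id", "axis_mm")])
  if (anyDuplicated(ax$section_id)) abort_validation("axis_mm is not constant within a section")
  invisible(cells)
}
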