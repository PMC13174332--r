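#' Read a counts matrix from MTX or dense CSV
#'
#' `read_counts_mtx()` reads a MatrixMarket sparse matrix (genes x cells or
#' cells x genes; orientation inferred from the id files) with its
#' accompanying gene and barcode TSVs (one id per line, first column used).
#' `read_counts_csv()` reads a dense CSV with cell ids in the first column
#' and gene ids in the header. Both return a cell x gene matrix with
#' dimnames, the orientation every function in this package expects.
#'
#' @param mtx_path MatrixMarket file.
#' @param genes_path,cells_path TSV files of gene ids and cell barcodes.
#' @return Cell x gene matrix (sparse for MTX, dense for CSV).
#' @export
read_counts_mtx <- function(mtx_path, genes_path, cells_path) {
  m <- Matrix::readMM(mtx_path)
  genes <- readr::read_tsv(genes_path, col_names = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))[[1]]
  cells <- readr::read_tsv(cells_path, col_names = FALSE, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))[[1]]
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    m <- Matrix::t(m)  # 10x convention: genes x cells on disk
  } else if (!(nrow(m) == length(cells) && ncol(m) == length(genes))) {
    abort(sprintf("matrix is %d x %d but there are %d gene and %d cell ids",
                  nrow(m), ncol(m), length(genes), length(cells)))
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(cells, genes)
  m
}

#' @rdname read_counts_mtx
#' @param csv_path Dense CSV (first column cell ids, header gene ids).
#' @export
read_counts_csv <- function(csv_path) {
  df <- readr::read_csv(csv_path, progress = FALSE, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a counts matrix as MTX plus id files
#'
#' @param counts Cell x gene matrix.
#' @param out_dir Output directory (created if needed); writes
#'   `matrix.mtx`, `genes.tsv`, `barcodes.tsv` in the 10x genes x cells
#'   orientation.
#' @return `out_dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::t(Matrix::Matrix(counts, sparse = TRUE)), "generalMatrix")
  Matrix::writeMM(m, file.path(out_dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(out_dir, "genes.tsv"))
  writeLines(rownames(counts), file.path(out_dir, "barcodes.tsv"))
  invisible(out_dir)
}
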