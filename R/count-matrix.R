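#' Single-cell count matrix container
#'
#' Lightweight container for a cells x genes sparse count matrix with cell
#' barcodes, gene identifiers and a per-cell batch label. Counts are stored
#' as a `Matrix::dgCMatrix` with cells in rows, matching the orientation used
#' by all downstream operations; on disk the Matrix Market triplet is written
#' genes x cells, the convention of CellRanger-style output.
#'
#' @param counts non-negative integer matrix (cells x genes), dense or sparse.
#' @param cell_ids character vector of unique cell barcodes (rows).
#' @param gene_ids character vector of gene identifiers (columns).
#' @param batch per-cell batch label (coerced to factor); defaults to a
#'   single batch.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   (dgCMatrix), `cell_ids`, `gene_ids` and `batch`.
#' @export
count_matrix <- function(counts, cell_ids = rownames(counts),
                         gene_ids = colnames(counts), batch = NULL) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%05d", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- sprintf("G%04d", seq_len(ncol(counts)))
  if (is.null(batch)) batch <- rep("b1", nrow(counts))
  stopifnot(length(cell_ids) == nrow(counts),
            length(gene_ids) == ncol(counts),
            length(batch) == nrow(counts))
  if (anyDuplicated(cell_ids)) stop("cell barcodes must be unique")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids), batch = factor(batch)),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes, %d batch(es)\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$batch)))
  invisible(x)
}

#' Subset a count matrix by cells and/or genes
#'
#' @param x a `count_matrix`.
#' @param cells,genes logical or integer index over cells (rows) / genes
#'   (columns); `NULL` keeps all.
#' @return a `count_matrix` with order preserved.
#' @export
subset_count_matrix <- function(x, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_len(nrow(x$counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$counts))
  count_matrix(x$counts[cells, genes, drop = FALSE],
               cell_ids = x$cell_ids[cells], gene_ids = x$gene_ids[genes],
               batch = as.character(x$batch)[cells])
}

#' Flag mitochondrial and ribosomal genes by name
#'
#' Genes are flagged by the standard naming convention: mitochondrial genes
#' carry an `MT-` prefix and cytosolic ribosomal protein genes an `RPL` or
#' `RPS` prefix. The joint flagged fraction feeds the 20% cell filter.
#'
#' @param gene_ids character vector of gene identifiers.
#' @return logical vector, `TRUE` for flagged genes.
#' @export
flag_mito_ribo <- function(gene_ids) {
  grepl("^MT-|^RPL|^RPS", gene_ids, ignore.case = FALSE)
}

#' Write a count matrix as a CellRanger-style Matrix Market triplet directory
#'
#' Writes `matrix.mtx` (genes x cells, 1-based indices, integer entries),
#' `barcodes.tsv`, `features.tsv` (id and name columns) and `batches.tsv`.
#'
#' @param x a `count_matrix`.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_mtx_dir <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(Matrix::t(x$counts), "TsparseMatrix")  # genes x cells
  path <- file.path(dir, "matrix.mtx")
  con <- file(path, "w")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
  close(con)
  trip <- data.table::data.table(i = m@i + 1L, j = m@j + 1L,
                                 x = as.integer(m@x))
  data.table::fwrite(trip, path, sep = " ", col.names = FALSE, append = TRUE)
  writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  utils::write.table(data.frame(id = x$gene_ids, name = x$gene_ids),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(barcode = x$cell_ids,
                                batch = as.character(x$batch)),
                     file.path(dir, "batches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a Matrix Market triplet directory into a count matrix
#'
#' Expects `matrix.mtx` (genes x cells), `barcodes.tsv` and `features.tsv`;
#' an optional `batches.tsv` (columns `barcode`, `batch`) supplies batch
#' labels.
#'
#' @param dir directory containing the triplet files.
#' @return a `count_matrix` (cells x genes).
#' @export
read_mtx_dir <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             header = FALSE, stringsAsFactors = FALSE)
  batch <- NULL
  bfile <- file.path(dir, "batches.tsv")
  if (file.exists(bfile)) {
    bt <- utils::read.table(bfile, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    batch <- bt$batch[match(barcodes, bt$barcode)]
  }
  count_matrix(Matrix::t(m), cell_ids = barcodes, gene_ids = feats[[1]],
               batch = batch)
}
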