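#' Cell and gene quality-control thresholds
#'
#' Defaults are the study's filters: cells must detect between 200 and 4000
#' genes, have at most 15,000 total counts and at most 20% of counts from
#' mitochondrial/ribosomal genes (assessed jointly); genes must be detected
#' in at least 3 cells. All thresholds are inclusive on the "keep" side.
#'
#' @param min_genes,max_genes bounds on the number of detected genes.
#' @param max_counts upper bound on total counts per cell.
#' @param max_mito_ribo_frac upper bound on the flagged-gene count fraction.
#' @param min_cells minimum number of cells a gene must be detected in.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 4000,
                          max_counts = 15000, max_mito_ribo_frac = 0.20,
                          min_cells = 3) {
  stopifnot(min_genes < max_genes, min_genes >= 0, max_counts >= 0,
            max_mito_ribo_frac >= 0, min_cells >= 0)
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_counts = max_counts,
                 max_mito_ribo_frac = max_mito_ribo_frac,
                 min_cells = min_cells), class = "qc_thresholds")
}

#' Per-cell QC statistics
#'
#' Computes, for every cell, the number of detected genes (count > 0), the
#' total count, and the fraction of counts coming from flagged
#' (mitochondrial/ribosomal) genes. An all-zero cell has a flagged fraction
#' of 0 by definition (it fails the `min_genes` filter regardless).
#'
#' @param m a [count_matrix()].
#' @param flagged_genes character vector of flagged gene ids (subset of
#'   `m$gene_ids`); default flags by name via [flag_mito_ribo()].
#' @return data.frame with one row per cell: `barcode`, `n_genes_detected`,
#'   `total_counts`, `mito_ribo_frac`.
#' @export
compute_cell_qc <- function(m, flagged_genes = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  if (is.null(flagged_genes)) {
    flagged_genes <- m$gene_ids[flag_mito_ribo(m$gene_ids)]
  } else {
    unknown <- setdiff(flagged_genes, m$gene_ids)
    if (length(unknown))
      stop("flagged gene(s) not in the matrix: ",
           paste(unknown, collapse = ", "))
  }
  total <- Matrix::rowSums(m$counts)
  ngene <- Matrix::rowSums(m$counts > 0)
  fl <- m$gene_ids %in% flagged_genes
  fl_counts <- if (any(fl)) Matrix::rowSums(m$counts[, fl, drop = FALSE]) else
    numeric(nrow(m$counts))
  frac <- ifelse(total > 0, fl_counts / total, 0)
  data.frame(barcode = m$cell_ids, n_genes_detected = as.integer(ngene),
             total_counts = as.numeric(total), mito_ribo_frac = frac,
             stringsAsFactors = FALSE)
}

#' Filter cells on QC thresholds
#'
#' A cell is kept iff `min_genes <= n_genes_detected <= max_genes`,
#' `total_counts <= max_counts` and `mito_ribo_frac <= max_mito_ribo_frac`
#' (all inclusive). Cell order is preserved.
#'
#' @param m a [count_matrix()].
#' @param stats per-cell statistics from [compute_cell_qc()], aligned to `m`.
#' @param t a [qc_thresholds()].
#' @return list with `matrix` (the filtered [count_matrix()]), `keep`
#'   (logical mask over input cells) and `failing` (character: first failing
#'   criterion per cell, `""` if kept).
#' @export
filter_cells <- function(m, stats = compute_cell_qc(m), t = qc_thresholds()) {
  stopifnot(inherits(m, "count_matrix"), nrow(stats) == nrow(m$counts),
            all(stats$barcode == m$cell_ids))
  fail <- character(nrow(stats))
  fail[stats$mito_ribo_frac > t$max_mito_ribo_frac] <- "max_mito_ribo_frac"
  fail[stats$total_counts > t$max_counts] <- "max_counts"
  fail[stats$n_genes_detected > t$max_genes] <- "max_genes"
  fail[stats$n_genes_detected < t$min_genes] <- "min_genes"
  keep <- fail == ""
  if (!any(keep))
    stop("no cells pass the QC thresholds; review the thresholds")
  list(matrix = subset_count_matrix(m, cells = keep), keep = keep,
       failing = fail)
}

#' Filter genes on a minimum detection count
#'
#' A gene is kept iff it is detected (count > 0) in at least `min_cells`
#' cells (inclusive). Gene order is preserved.
#'
#' @param m a [count_matrix()].
#' @param min_cells detection threshold (>= 0).
#' @return list with `matrix` (the filtered [count_matrix()]) and `keep`
#'   (logical mask over input genes).
#' @export
filter_genes <- function(m, min_cells = 3) {
  stopifnot(inherits(m, "count_matrix"), min_cells >= 0)
  ncells <- Matrix::colSums(m$counts > 0)
  keep <- ncells >= min_cells
  list(matrix = subset_count_matrix(m, genes = keep), keep = keep)
}

#' Write the per-cell QC report
#'
#' One row per input cell: barcode, QC statistics, kept flag and the failing
#' criterion (empty when kept).
#'
#' @param stats per-cell statistics from [compute_cell_qc()].
#' @param filt result of [filter_cells()] on the same cells.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(stats, filt, path) {
  rep <- cbind(stats, kept = filt$keep, failing_criterion = filt$failing)
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
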