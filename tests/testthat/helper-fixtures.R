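# Small builders shared across test files.

# Dense matrix -> count_matrix with default ids.
cm_from_dense <- function(m, batch = NULL, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- sprintf("G%03d", seq_len(ncol(m)))
  count_matrix(m, cell_ids = sprintf("c%03d", seq_len(nrow(m))),
               gene_ids = gene_ids, batch = batch)
}

# A small single-cell simulation config that keeps tests fast.
small_sc_config <- function(seed = 1, n_cells = 1500, n_genes = 500,
                            n_clusters = 8, ...) {
  sc_sim_config(n_cells = n_cells, n_genes = n_genes,
                n_clusters = n_clusters, n_signature = 25,
                n_treg_signature = 30, n_shared_program = 15,
                seed = seed, ...)
}

# Wrap a plain label vector as a cluster_assignment (for marker tests that
# construct clusters by hand).
manual_clusters <- function(labels) {
  labels <- as.integer(labels)
  structure(list(labels = labels, resolution = NA_real_,
                 n_clusters = length(unique(labels))),
            class = "cluster_assignment")
}

# Best-matching detected cluster for a set of true member cells (by
# Jaccard); returns c(label, jaccard).
best_jaccard <- function(true_cells, labels, cell_ids) {
  stopifnot(length(labels) == length(cell_ids))
  best <- c(label = NA_real_, jaccard = 0)
  for (l in unique(labels)) {
    det <- cell_ids[labels == l]
    j <- length(intersect(true_cells, det)) /
      length(union(true_cells, det))
    if (j > best["jaccard"]) best <- c(label = l, jaccard = j)
  }
  best
}

# Run the single-cell stage chain on a simulated dataset and return the
# pieces recovery tests need. Mirrors run_sc_pipeline without file I/O.
run_sc_chain <- function(sim, n_hvg = 1000, n_pcs = 50, k = 15,
                         resolution = 1.5, seed = 1,
                         qc = qc_thresholds(min_genes = 20)) {
  m <- sim$matrix
  fc <- filter_cells(m, compute_cell_qc(m), qc)
  fg <- filter_genes(fc$matrix)
  nm <- normalize_log(fg$matrix)
  hv <- select_hvg(nm, min(n_hvg, ncol(nm$values)))
  emb <- pca_embed(as.matrix(nm$values[, hv, drop = FALSE]),
                   min(n_pcs, length(hv)))
  emb <- center_batches(emb, fg$matrix$batch)
  g <- build_knn_graph(emb, k)
  ca <- detect_communities(g, resolution, seed = seed)
  truth <- sim$truth$true_cluster_of_cell[fg$matrix$cell_ids]
  list(matrix = fg$matrix, nm = nm, ca = ca, truth = truth)
}
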