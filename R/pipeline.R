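#' Run configuration for the single-cell pipeline
#'
#' Bundles the seed and all stage parameters. Validation happens at
#' construction, before any compute.
#'
#' @param seed single pipeline-level seed; all stage randomness derives
#'   from it.
#' @param qc a [qc_thresholds()].
#' @param scale_target normalization target (`NULL` = median total counts).
#' @param n_hvg number of highly variable genes.
#' @param n_pcs number of principal components.
#' @param k_neighbors neighbors for the kNN graph.
#' @param resolution Leiden resolution (> 0; the study used 1.5).
#' @param marker a [foxp3_call_config()].
#' @param marker_p_threshold BH-adjusted p cutoff for marker tables.
#' @param top_n markers kept per Treg cluster table.
#' @return list of class `sc_run_config`.
#' @export
sc_run_config <- function(seed = 1L, qc = qc_thresholds(),
                          scale_target = NULL, n_hvg = 1000, n_pcs = 50,
                          k_neighbors = 15, resolution = 1.5,
                          marker = foxp3_call_config(),
                          marker_p_threshold = 0.05, top_n = 50) {
  if (resolution <= 0) stop("resolution must be > 0")
  stopifnot(inherits(qc, "qc_thresholds"),
            inherits(marker, "foxp3_call_config"),
            n_hvg >= 1, n_pcs >= 1, k_neighbors >= 1)
  structure(list(seed = as.integer(seed), qc = qc,
                 scale_target = scale_target, n_hvg = n_hvg, n_pcs = n_pcs,
                 k_neighbors = k_neighbors, resolution = resolution,
                 marker = marker, marker_p_threshold = marker_p_threshold,
                 top_n = top_n), class = "sc_run_config")
}

new_run_log <- function(seed, params = list()) {
  list(created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"), seed = seed,
       params = params, stages = list())
}

log_stage <- function(log, name, ...) {
  rec <- c(list(stage = name,
                time = format(Sys.time(), "%Y-%m-%d %H:%M:%S")), list(...))
  log$stages[[length(log$stages) + 1]] <- rec
  log
}

write_run_log <- function(log, path) {
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

run_stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(c(sprintf("pipeline aborted in stage '%s'", name),
                 conditionMessage(e)),
               file.path(out_dir, "INCOMPLETE"))
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the single-cell pipeline
#'
#' Stage order follows the study's workflow: QC filtering, normalization,
#' highly-variable-gene selection, PCA, per-batch centering, kNN graph,
#' Leiden clustering, FOXP3-cluster identification and marker scoring. All
#' stage outputs plus a machine-readable run log are written to `out_dir`;
#' re-running with an identical configuration and input reproduces
#' identical tables.
#'
#' @param input a [count_matrix()] or the path of a Matrix Market triplet
#'   directory (read via [read_mtx_dir()]).
#' @param cfg an [sc_run_config()].
#' @param out_dir output directory, created if missing.
#' @return (invisibly) list with the filtered matrix, normalized matrix,
#'   embedding, cluster assignment, FOXP3 calls, marker tables and the
#'   path of each written artifact.
#' @export
run_sc_pipeline <- function(input, cfg = sc_run_config(), out_dir) {
  stopifnot(inherits(cfg, "sc_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "INCOMPLETE"))
  log <- new_run_log(cfg$seed, params = list(
    resolution = cfg$resolution, n_hvg = cfg$n_hvg, n_pcs = cfg$n_pcs,
    k_neighbors = cfg$k_neighbors))
  m <- run_stage("load", out_dir, {
    if (is.character(input)) {
      hashes <- tools::md5sum(list.files(input, full.names = TRUE))
      log <- log_stage(log, "load", input = input,
                       input_md5 = as.list(hashes))
      read_mtx_dir(input)
    } else {
      log <- log_stage(log, "load", input = "in-memory count_matrix")
      input
    }
  })

  filt <- run_stage("qc", out_dir, {
    stats <- compute_cell_qc(m)
    fc <- filter_cells(m, stats, cfg$qc)
    fg <- filter_genes(fc$matrix, cfg$qc$min_cells)
    write_qc_report(stats, fc, file.path(out_dir, "qc_report.tsv"))
    removed <- table(factor(fc$failing[fc$failing != ""],
                            levels = c("min_genes", "max_genes",
                                       "max_counts", "max_mito_ribo_frac")))
    log <- log_stage(log, "qc", cells_in = nrow(m$counts),
                     cells_kept = sum(fc$keep),
                     cells_removed = as.list(removed),
                     genes_in = ncol(m$counts),
                     genes_kept = sum(fg$keep))
    fg$matrix
  })
  write_mtx_dir(filt, file.path(out_dir, "filtered_matrix"))

  nm <- run_stage("normalize", out_dir, normalize_log(filt, cfg$scale_target))
  log <- log_stage(log, "normalize", scale_target = nm$scale_target)

  hvg <- run_stage("hvg", out_dir, select_hvg(nm, cfg$n_hvg))
  log <- log_stage(log, "hvg", n_hvg = length(hvg))

  emb <- run_stage("pca", out_dir, {
    set.seed(cfg$seed)
    pca_embed(as.matrix(nm$values[, hvg, drop = FALSE]), cfg$n_pcs)
  })
  emb <- run_stage("batch_center", out_dir, center_batches(emb, filt$batch))
  log <- log_stage(log, "pca_batch_center", n_pcs = emb$n_components,
                   n_batches = nlevels(filt$batch))

  graph <- run_stage("knn", out_dir, build_knn_graph(emb, cfg$k_neighbors))
  ca <- run_stage("cluster", out_dir,
                  detect_communities(graph, cfg$resolution,
                                     seed = cfg$seed))
  log <- log_stage(log, "cluster", resolution = cfg$resolution,
                   n_clusters = ca$n_clusters)
  utils::write.table(data.frame(barcode = filt$cell_ids,
                                cluster = ca$labels),
                     file.path(out_dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emb_df <- data.frame(barcode = filt$cell_ids, round(emb$coords, 6))
  names(emb_df)[-1] <- sprintf("PC%d", seq_len(emb$n_components))
  utils::write.table(emb_df, file.path(out_dir, "embedding.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  calls <- run_stage("foxp3", out_dir,
                     identify_foxp3_clusters(nm, filt, ca, cfg$marker))
  utils::write.table(calls$evidence, file.path(out_dir, "foxp3_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- log_stage(log, "foxp3", called = as.list(calls$clusters))

  stats <- cluster_gene_stats(nm, filt, ca)
  markers <- list()
  for (cl in calls$clusters) {
    tab <- run_stage("markers", out_dir,
                     rank_markers_from_stats(nm, filt, ca, stats, cl,
                                             top_n = cfg$top_n,
                                             p_threshold = cfg$marker_p_threshold))
    tab_out <- tab
    tab_out[c("p_wilcoxon", "padj", "ratio_score", "lfc", "pct_in",
              "pct_rest")] <-
      lapply(tab_out[c("p_wilcoxon", "padj", "ratio_score", "lfc",
                       "pct_in", "pct_rest")], signif, 8)
    utils::write.table(tab_out,
                       file.path(out_dir,
                                 sprintf("markers_cluster%02d.tsv", cl)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    markers[[as.character(cl)]] <- tab
  }
  log <- log_stage(log, "markers",
                   n_markers = as.list(stats::setNames(
                     vapply(markers, nrow, 0L), names(markers))))

  # dot-plot summary for the scored marker genes plus FOXP3
  dot_genes <- unique(c(cfg$marker$foxp3_gene,
                        unlist(lapply(markers, function(t) t$gene))))
  dot_genes <- intersect(dot_genes, colnames(stats$mean_expr))
  if (length(dot_genes)) {
    dp <- expand.grid(cluster = rownames(stats$mean_expr),
                      gene = dot_genes, stringsAsFactors = FALSE)
    dp$mean_expr <- signif(stats$mean_expr[cbind(dp$cluster, dp$gene)], 8)
    dp$pct_expressing <- signif(
      stats$pct_expressing[cbind(dp$cluster, dp$gene)], 8)
    utils::write.table(dp, file.path(out_dir, "dotplot_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_run_log(log, file.path(out_dir, "run_log.json"))
  invisible(list(matrix = filt, normalized = nm, embedding = emb,
                 clusters = ca, foxp3 = calls, markers = markers,
                 stats = stats, out_dir = out_dir))
}

#' Read a genes x samples bulk count CSV
#'
#' First column `gene`, remaining columns one per sample.
#'
#' @param path CSV path.
#' @return integer matrix with gene rownames.
#' @export
read_bulk_counts <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Run the bulk differential-expression pipeline
#'
#' Wraps [bulk_de()]: size factors, moderated dispersions, NB GLM fits,
#' Wald and likelihood-ratio tests, BH adjustment; writes per-contrast
#' result tables, size factors, the Z-score heatmap matrix of normalized
#' group means, Venn region counts (up and down at the padj cutoff) and a
#' run log.
#'
#' @param counts genes x samples matrix or a counts CSV path
#'   ([read_bulk_counts()]).
#' @param meta metadata data.frame or a TSV path (columns sample, sex,
#'   cd25_group).
#' @param out_dir output directory.
#' @param padj_cutoff significance cutoff used for the Venn partition.
#' @param seed recorded in the run log (the engine itself is
#'   deterministic).
#' @return (invisibly) the [bulk_de()] result with `venn` attached.
#' @export
run_bulk_pipeline <- function(counts, meta, out_dir, padj_cutoff = 0.05,
                              seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "INCOMPLETE"))
  log <- new_run_log(seed, params = list(padj_cutoff = padj_cutoff))
  if (is.character(counts)) {
    log <- log_stage(log, "load_counts", input = counts,
                     md5 = unname(tools::md5sum(counts)))
    counts <- read_bulk_counts(counts)
  }
  if (is.character(meta)) {
    log <- log_stage(log, "load_meta", input = meta,
                     md5 = unname(tools::md5sum(meta)))
    meta <- utils::read.table(meta, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  }
  de <- run_stage("bulk_de", out_dir,
                  bulk_de(counts, meta, p_threshold = padj_cutoff))
  log <- log_stage(log, "bulk_de", n_genes = nrow(counts),
                   n_samples = ncol(counts),
                   size_factors = as.list(signif(de$size_factors, 8)))
  utils::write.table(data.frame(sample = names(de$size_factors),
                                size_factor = signif(de$size_factors, 8)),
                     file.path(out_dir, "size_factors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (cn in names(de$results)) {
    tab <- de$results[[cn]]
    num <- c("base_mean", "lfc", "wald_stat", "p_wald", "p_lrt", "padj",
             "padj_lrt")
    tab[num] <- lapply(tab[num], signif, 8)
    utils::write.table(tab, file.path(out_dir,
                                      sprintf("results_%s.tsv", cn)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  zs <- zscore_expression(de$cond_means)
  utils::write.table(data.frame(gene = rownames(zs), signif(zs, 8)),
                     file.path(out_dir, "zscore_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  venn <- list(up = contrast_overlap_sets(de$results, padj_cutoff, "up"),
               down = contrast_overlap_sets(de$results, padj_cutoff,
                                            "down"))
  jsonlite::write_json(
    list(padj_cutoff = padj_cutoff,
         up = as.list(venn$up$counts), down = as.list(venn$down$counts),
         genes_up = venn$up$genes, genes_down = venn$down$genes),
    file.path(out_dir, "venn.json"), auto_unbox = TRUE, pretty = TRUE)
  log <- log_stage(log, "venn", up = as.list(venn$up$counts),
                   down = as.list(venn$down$counts))
  write_run_log(log, file.path(out_dir, "run_log.json"))
  de$venn <- venn
  invisible(de)
}

#' Read and validate a qPCR CT table
#'
#' Expects columns `sample`, `group`, `ct_target`, `ct_reference`. A row
#' whose CT fields cannot be parsed as numbers raises an error naming the
#' offending line (1-based, header included).
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("sample", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(df)))
    stop("qPCR table needs columns ", paste(need, collapse = ", "))
  for (col in c("ct_target", "ct_reference")) {
    raw <- trimws(df[[col]])
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & nzchar(raw) & raw != "NA")
    if (length(bad))
      stop(sprintf("malformed qPCR row at line %d: %s = '%s'",
                   bad[1] + 1L, col, raw[bad[1]]))
    df[[col]] <- num
  }
  if (any(!nzchar(trimws(df$group))))
    stop("empty group label in qPCR table")
  df
}

#' Run the qPCR quantification pipeline
#'
#' Delta-CT normalization, delta-delta-CT fold changes against the control
#' group, and one-way ANOVA with Tukey HSD comparisons of the per-sample
#' fold changes (the analysis scale of the study's fold-change figures;
#' set `analysis_scale = "log"` to compare -ddct values instead).
#'
#' @param table data.frame or CSV path ([read_qpcr_table()]).
#' @param control_group control group label.
#' @param out_dir output directory.
#' @param analysis_scale `"fold"` (default) or `"log"`.
#' @return (invisibly) list with `folds` ([ddct_fold_change()] result) and
#'   `comparison` ([anova_tukey()] result).
#' @export
run_qpcr <- function(table, control_group, out_dir,
                     analysis_scale = c("fold", "log")) {
  analysis_scale <- match.arg(analysis_scale)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "INCOMPLETE"))
  log <- new_run_log(NA, params = list(control_group = control_group,
                                       analysis_scale = analysis_scale))
  if (is.character(table)) {
    log <- log_stage(log, "load", input = table,
                     md5 = unname(tools::md5sum(table)))
    table <- read_qpcr_table(table)
  }
  if (any(!nzchar(trimws(table$group))))
    stop("empty group label in qPCR table")
  dct <- run_stage("delta_ct", out_dir, delta_ct(table))
  fc <- run_stage("ddct", out_dir, ddct_fold_change(dct, control_group))
  vals <- if (analysis_scale == "fold") fc$per_sample$fold else
    -fc$per_sample$ddct
  cmp <- run_stage("anova_tukey", out_dir,
                   anova_tukey(vals, fc$per_sample$group))
  per <- fc$per_sample
  per[c("dct", "ddct", "fold")] <- lapply(per[c("dct", "ddct", "fold")],
                                          signif, 8)
  utils::write.table(per, file.path(out_dir, "per_sample_folds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pw <- cmp$pairwise
  pw[c("diff", "p_tukey")] <- lapply(pw[c("diff", "p_tukey")], signif, 8)
  utils::write.table(pw, file.path(out_dir, "group_comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- log_stage(log, "anova", f_stat = cmp$f_stat,
                   p_omnibus = cmp$p_omnibus)
  write_run_log(log, file.path(out_dir, "run_log.json"))
  invisible(list(folds = fc, comparison = cmp))
}
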