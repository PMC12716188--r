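#' Configuration for the synthetic single-cell dataset
#'
#' The generator emulates the structure the single-cell analysis assumes:
#' a few thousand CD4+ cells in ~20 clusters, two of which are rare
#' FOXP3-positive (Treg) clusters, each enriched for a designated marker
#' panel. Counts are negative-binomial with mean `mu` and dispersion `alpha`
#' (variance `mu + alpha * mu^2`), the same parameterization the bulk DE
#' engine uses. Per-cell library sizes vary log-normally so that scaling
#' normalization is non-trivially exercised; batches add a per-gene
#' log-scale location shift.
#'
#' Cluster identity is encoded through planted expression programs:
#' * each Treg cluster gets a 10-gene marker panel at `panel_fold`
#'   (the genes the ratio score should recover), a broad but subtle unique
#'   program (`n_treg_signature` genes at folds in `treg_signature_fold`),
#'   and a shared Treg program (`n_shared_program` genes at `shared_fold`)
#'   expressed in both Treg clusters;
#' * every other cluster gets its own program of `n_signature` genes at
#'   folds drawn from `signature_fold`.
#' A designated `FOXP3` gene has a low baseline (so that fewer than 10% of
#' cells express it outside the Treg clusters) and is elevated in both Treg
#' clusters, more strongly in the first.
#'
#' @param n_cells,n_genes,n_clusters dataset dimensions (defaults 5000 cells,
#'   2000 genes, 22 clusters - a desk-scale rendition of ~20,000 cells in
#'   23 clusters).
#' @param treg_cluster_fracs fractions of cells in the Treg clusters
#'   (defaults 0.041 and 0.030, the reported sizes of the two FOXP3+
#'   clusters).
#' @param marker_panel data.frame with columns `gene`, `cluster` (Treg
#'   cluster index) and `fold` (>= 1); default [default_marker_panel()].
#' @param baseline_mean mean count per gene per cell on the linear scale;
#'   per-gene baselines are drawn log-normally around it.
#' @param dispersion negative-binomial dispersion alpha (> 0).
#' @param n_batches,batch_shift number of batches and the standard deviation
#'   of the per-gene log-scale batch offset.
#' @param frac_mito_ribo_genes fraction of genes flagged as mitochondrial /
#'   ribosomal (named with `MT-` / `RPL` prefixes).
#' @param sf_sigma log-normal standard deviation of per-cell size factors.
#' @param n_signature,signature_fold program size and fold range for
#'   non-Treg clusters.
#' @param n_treg_signature,treg_signature_fold unique program size and fold
#'   range for each Treg cluster.
#' @param n_shared_program,shared_fold shared Treg program size and fold.
#' @param foxp3_gene,foxp3_baseline,foxp3_folds designated FOXP3 gene id,
#'   its baseline mean, and its fold elevation in the two Treg clusters.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return a validated list of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_cells = 5000, n_genes = 2000, n_clusters = 22,
                          treg_cluster_fracs = c(0.041, 0.030),
                          marker_panel = default_marker_panel(),
                          baseline_mean = 0.5, dispersion = 1.0,
                          n_batches = 2, batch_shift = 0.15,
                          frac_mito_ribo_genes = 0.08, sf_sigma = 0.3,
                          n_signature = 60, signature_fold = c(4, 9),
                          n_treg_signature = 80, treg_signature_fold = c(3, 5),
                          n_shared_program = 40, shared_fold = 5,
                          foxp3_gene = "FOXP3", foxp3_baseline = 0.02,
                          foxp3_folds = c(40, 20), seed = 1L) {
  n_treg <- length(treg_cluster_fracs)
  if (n_clusters < 3) stop("n_clusters must be >= 3")
  if (n_treg < 1 || n_treg >= n_clusters)
    stop("need at least one Treg cluster and fewer Treg than total clusters")
  if (any(treg_cluster_fracs * n_cells < 20))
    stop("a Treg cluster fraction times n_cells is below 20 cells; ",
         "too small to test - increase n_cells or the fraction")
  if (!all(c("gene", "cluster", "fold") %in% names(marker_panel)))
    stop("marker_panel needs columns gene, cluster, fold")
  if (any(marker_panel$fold < 1)) stop("all fold-elevations must be >= 1")
  if (any(foxp3_folds < 1) || length(foxp3_folds) != n_treg)
    stop("foxp3_folds must have one entry >= 1 per Treg cluster")
  if (dispersion <= 0) stop("dispersion must be > 0")
  n_other <- n_clusters - n_treg
  w <- seq(1, 2.2, length.out = n_other)
  cluster_fracs <- c(treg_cluster_fracs, (1 - sum(treg_cluster_fracs)) * w / sum(w))
  stopifnot(abs(sum(cluster_fracs) - 1) < 1e-9)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters),
                 treg_cluster_fracs = treg_cluster_fracs,
                 cluster_fracs = cluster_fracs, marker_panel = marker_panel,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 n_batches = as.integer(n_batches), batch_shift = batch_shift,
                 frac_mito_ribo_genes = frac_mito_ribo_genes,
                 sf_sigma = sf_sigma, n_signature = n_signature,
                 signature_fold = signature_fold,
                 n_treg_signature = n_treg_signature,
                 treg_signature_fold = treg_signature_fold,
                 n_shared_program = n_shared_program, shared_fold = shared_fold,
                 foxp3_gene = foxp3_gene, foxp3_baseline = foxp3_baseline,
                 foxp3_folds = foxp3_folds, seed = as.integer(seed)),
            class = "sc_sim_config")
}

#' Default Treg marker panels
#'
#' Ten genes per Treg cluster at fold elevation 8, named after canonical
#' Treg-associated genes (CTLA4, TNFRSF18/GITR, IL2RA/CD25, SIVA1, ITGB8,
#' ...). These are the genes the mean-expression-ratio score is expected to
#' rank at the top of each Treg cluster's marker list.
#'
#' @param fold fold elevation of panel genes in their target cluster.
#' @return data.frame with columns `gene`, `cluster`, `fold`.
#' @export
default_marker_panel <- function(fold = 8) {
  data.frame(
    gene = c("SIVA1", "CTLA4", "TNFRSF18", "IL2RA", "IKZF2",
             "TGFB1", "CD274", "CCR8", "LAG3", "IL10",
             "ITGB8", "DUSP14", "FAS", "PDCD1", "CXCR5",
             "CD28", "IL7R", "ITGA4", "TNFA", "BST2"),
    cluster = rep(1:2, each = 10),
    fold = fold)
}

#' Simulate a single-cell count dataset with planted Treg clusters
#'
#' Draws cluster assignments multinomially from the configured fractions,
#' builds a per-gene x per-cluster mean model from the planted programs, and
#' samples negative-binomial counts with per-cell log-normal size factors
#' and per-batch log-scale offsets. Deterministic for a fixed seed.
#'
#' @param cfg an [sc_sim_config()].
#' @return list with elements `matrix` (a [count_matrix()]) and `truth`, a
#'   list recording `true_cluster_of_cell` (integer 1..n_clusters, named by
#'   barcode), `treg_clusters` (always `1:length(treg_cluster_fracs)`),
#'   `planted_markers` (marker panel genes per Treg cluster),
#'   `signature_genes` (full program per cluster), `shared_program`,
#'   `foxp3_gene`, and the per-gene baseline means and fold matrix.
#' @export
simulate_sc_dataset <- function(cfg = sc_sim_config()) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  set.seed(cfg$seed)
  n_treg <- length(cfg$treg_cluster_fracs)
  K <- cfg$n_clusters; G <- cfg$n_genes; N <- cfg$n_cells
  sizes <- drop(stats::rmultinom(1, N, cfg$cluster_fracs))
  if (any(sizes[seq_len(n_treg)] < 20))
    stop("a sampled Treg cluster has fewer than 20 cells")
  truth_cl <- sample(rep(seq_len(K), sizes))

  gid <- sprintf("G%04d", seq_len(G))
  n_mt <- round(cfg$frac_mito_ribo_genes * G / 3)
  n_rb <- round(cfg$frac_mito_ribo_genes * G * 2 / 3)
  mt_idx <- seq_len(n_mt)
  rb_idx <- n_mt + seq_len(n_rb)
  gid[mt_idx] <- sprintf("MT-%04d", seq_along(mt_idx))
  gid[rb_idx] <- sprintf("RPL%04d", seq_along(rb_idx))
  base <- cfg$baseline_mean * exp(stats::rnorm(G, 0, 1) - 0.5)
  # mito/ribo genes are count-rich; multipliers put the average cell's
  # flagged fraction near 14%, so the 20% QC filter trims only the tail
  base[mt_idx] <- base[mt_idx] * 3
  base[rb_idx] <- base[rb_idx] * 1.5

  pool <- setdiff(seq_len(G), c(mt_idx, rb_idx))
  fox <- pool[1]
  gid[fox] <- cfg$foxp3_gene
  base[fox] <- cfg$foxp3_baseline
  pool <- pool[-1]
  panel <- cfg$marker_panel
  panel_idx <- pool[seq_len(nrow(panel))]
  gid[panel_idx] <- panel$gene
  base[panel_idx] <- cfg$baseline_mean
  pool <- pool[-seq_len(nrow(panel))]
  shared_idx <- pool[seq_len(cfg$n_shared_program)]
  base[shared_idx] <- cfg$baseline_mean
  sig_pool <- pool[-seq_len(cfg$n_shared_program)]

  fold <- matrix(1, G, K)
  fold[fox, seq_len(n_treg)] <- cfg$foxp3_folds
  fold[cbind(panel_idx, panel$cluster)] <- panel$fold
  fold[shared_idx, seq_len(n_treg)] <- cfg$shared_fold
  signature <- vector("list", K)
  for (k in seq_len(n_treg)) {
    sg <- sample(sig_pool, cfg$n_treg_signature)
    fold[sg, k] <- pmax(fold[sg, k],
                        stats::runif(cfg$n_treg_signature,
                                     cfg$treg_signature_fold[1],
                                     cfg$treg_signature_fold[2]))
    # fixed moderate baseline: on the log-ratio score scale the unique
    # program (folds <= 5) then ranks strictly below the marker panel
    # (fold 8), which is the structure the marker score is meant to find
    base[sg] <- cfg$baseline_mean
    signature[[k]] <- gid[sg]
  }
  for (k in seq_len(K - n_treg)) {
    sg <- sample(sig_pool, cfg$n_signature)
    fold[sg, k + n_treg] <- stats::runif(cfg$n_signature,
                                         cfg$signature_fold[1],
                                         cfg$signature_fold[2])
    signature[[k + n_treg]] <- gid[sg]
  }

  batch <- sample(rep_len(seq_len(cfg$n_batches), N))
  bshift <- matrix(stats::rnorm(G * cfg$n_batches, 0, cfg$batch_shift),
                   G, cfg$n_batches)
  bshift[, 1] <- 0
  sf_cell <- exp(stats::rnorm(N, 0, cfg$sf_sigma))
  mu <- t(base * fold[, truth_cl]) * sf_cell * t(exp(bshift[, batch]))
  counts <- matrix(stats::rnbinom(length(mu), size = 1 / cfg$dispersion,
                                  mu = mu), N, G)
  barcodes <- sprintf("cell%05d-%d", seq_len(N), batch)
  cm <- count_matrix(counts, cell_ids = barcodes, gene_ids = gid,
                     batch = sprintf("batch%d", batch))
  names(truth_cl) <- barcodes
  planted <- split(panel$gene, panel$cluster)
  truth <- structure(list(
    true_cluster_of_cell = truth_cl,
    treg_clusters = seq_len(n_treg),
    planted_markers = planted,
    signature_genes = signature,
    shared_program = gid[shared_idx],
    foxp3_gene = cfg$foxp3_gene,
    baseline_mean = stats::setNames(base, gid),
    fold_matrix = `dimnames<-`(fold, list(gid, NULL)),
    cluster_sizes = sizes), class = "sc_sim_truth")
  list(matrix = cm, truth = truth)
}

#' Configuration for the synthetic bulk RNA-seq dataset
#'
#' Emulates the CD25-sorted bulk design: three `cd25_group` levels
#' (negative / low / high) with `n_per_group` birds each and a balanced sex
#' covariate. The log2 mean of gene g in sample j is
#' `log2(baseline) + group_effect + sex_effect`, counts are
#' negative-binomial with dispersion `alpha`, and per-sample library sizes
#' vary log-normally.
#'
#' @param n_genes number of genes.
#' @param n_per_group replicates per CD25 group (the study used 4 birds).
#' @param group_effects numeric matrix `n_genes x 2` with columns `low` and
#'   `high`: planted log2 effects of the CD25 low / high levels relative to
#'   negative. Default all zero (a global null).
#' @param sex_effect per-gene log2 effect of sex (male relative to female);
#'   scalar or length `n_genes`. Default 0.
#' @param mean_range interval from which per-gene baseline means are drawn
#'   uniformly.
#' @param dispersion negative-binomial dispersion alpha (> 0).
#' @param sf_sigma log-normal sd of true per-sample size factors.
#' @param seed integer seed.
#' @return a validated list of class `bulk_sim_config`.
#' @export
bulk_sim_config <- function(n_genes = 2000, n_per_group = 4,
                            group_effects = NULL, sex_effect = 0,
                            mean_range = c(20, 2000), dispersion = 0.1,
                            sf_sigma = 0.3, seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (any(mean_range <= 0)) stop("planted means must be positive")
  if (is.null(group_effects)) group_effects <- matrix(0, n_genes, 2)
  group_effects <- as.matrix(group_effects)
  if (nrow(group_effects) != n_genes || ncol(group_effects) != 2)
    stop("group_effects must be an n_genes x 2 matrix (low, high)")
  colnames(group_effects) <- c("low", "high")
  sex_effect <- rep_len(sex_effect, n_genes)
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 group_effects = group_effects, sex_effect = sex_effect,
                 mean_range = mean_range, dispersion = dispersion,
                 sf_sigma = sf_sigma, seed = as.integer(seed)),
            class = "bulk_sim_config")
}

#' Simulate a bulk RNA-seq count dataset for the CD25 design
#'
#' @param cfg a [bulk_sim_config()].
#' @return list with `counts` (genes x samples integer matrix), `meta`
#'   (data.frame: sample, sex, cd25_group), `size_factors` (true per-sample
#'   library-size factors), and `truth` (list: `true_lfc` = the planted
#'   log2 effect matrix, `true_null_genes` = gene ids with no planted group
#'   effect, `sex_effect`).
#' @export
simulate_bulk_dataset <- function(cfg = bulk_sim_config()) {
  stopifnot(inherits(cfg, "bulk_sim_config"))
  set.seed(cfg$seed)
  n <- 3L * cfg$n_per_group
  grp <- factor(rep(c("negative", "low", "high"), each = cfg$n_per_group),
                levels = c("negative", "low", "high"))
  sex <- factor(rep(rep_len(c("F", "M"), cfg$n_per_group), 3),
                levels = c("F", "M"))
  samples <- sprintf("S%02d", seq_len(n))
  gid <- sprintf("G%04d", seq_len(cfg$n_genes))
  base <- stats::runif(cfg$n_genes, cfg$mean_range[1], cfg$mean_range[2])
  eff <- cbind(negative = 0, cfg$group_effects)[, as.character(grp)]
  lmu2 <- log2(base) + eff + outer(cfg$sex_effect, as.integer(sex == "M"))
  sf <- exp(stats::rnorm(n, 0, cfg$sf_sigma))
  sf <- sf / exp(mean(log(sf)))
  mu <- t(t(2^lmu2) * sf)
  if (any(mu <= 0)) stop("planted mean <= 0")
  counts <- matrix(stats::rnbinom(length(mu), size = 1 / cfg$dispersion,
                                  mu = mu), cfg$n_genes, n,
                   dimnames = list(gid, samples))
  null_genes <- gid[rowSums(abs(cfg$group_effects)) == 0]
  list(counts = counts,
       meta = data.frame(sample = samples, sex = as.character(sex),
                         cd25_group = as.character(grp),
                         stringsAsFactors = FALSE),
       size_factors = stats::setNames(sf, samples),
       truth = list(true_lfc = `rownames<-`(cfg$group_effects, gid),
                    true_null_genes = null_genes,
                    sex_effect = stats::setNames(cfg$sex_effect, gid)))
}

#' Simulate a qPCR CT table with group-level delta-CT shifts
#'
#' For each replicate the reference-gene CT is drawn around a fixed value
#' and the target CT is the reference CT plus the group's true delta-CT plus
#' Gaussian noise, so with `noise_sd = 0` the recovered delta-CT equals the
#' truth exactly.
#'
#' @param group_dcts named numeric vector: true delta-CT (target minus
#'   reference) per group.
#' @param noise_sd CT noise standard deviation (>= 0).
#' @param n_replicates replicates per group (>= 1).
#' @param seed integer seed.
#' @param ref_ct central reference-gene CT value.
#' @return data.frame with columns `sample`, `group`, `ct_target`,
#'   `ct_reference`.
#' @export
simulate_qpcr_dataset <- function(group_dcts, noise_sd = 0.1,
                                  n_replicates = 4, seed = 1L, ref_ct = 20) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (is.null(names(group_dcts))) stop("group_dcts must be named by group")
  set.seed(seed)
  out <- do.call(rbind, lapply(names(group_dcts), function(g) {
    ctr <- ref_ct + stats::rnorm(n_replicates, 0, noise_sd)
    ctt <- ctr + group_dcts[[g]] + stats::rnorm(n_replicates, 0, noise_sd)
    data.frame(sample = sprintf("%s_r%d", g, seq_len(n_replicates)),
               group = g, ct_target = ctt, ct_reference = ctr,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write a simulated bulk dataset to disk
#'
#' Counts go to `counts.csv` (rows = genes, first column `gene`), metadata
#' to `metadata.tsv`, and the planted truth to `truth_lfc.tsv`.
#'
#' @param bulk result of [simulate_bulk_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_bulk_dataset <- function(bulk, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(gene = rownames(bulk$counts), bulk$counts,
                              check.names = FALSE),
                   file.path(dir, "counts.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.table(bulk$meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = rownames(bulk$truth$true_lfc),
                                bulk$truth$true_lfc,
                                sex = bulk$truth$sex_effect),
                     file.path(dir, "truth_lfc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write the single-cell ground truth sidecar
#'
#' @param truth the `truth` element of [simulate_sc_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sc_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(barcode = names(truth$true_cluster_of_cell),
                                true_cluster = truth$true_cluster_of_cell),
                     file.path(dir, "truth_clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pm <- data.frame(cluster = rep(names(truth$planted_markers),
                                 lengths(truth$planted_markers)),
                   gene = unlist(truth$planted_markers, use.names = FALSE))
  utils::write.table(pm, file.path(dir, "truth_markers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
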