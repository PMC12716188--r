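#' Per-cluster, per-gene expression summaries
#'
#' For every (cluster, gene) pair: the mean expression on the normalized
#' log scale and the fraction of cells in the cluster expressing the gene
#' (raw count > 0). These two layers are kept explicit: means come from the
#' normalized values, percent-expressing from the raw counts.
#'
#' @param nm a [normalize_log()] result.
#' @param raw the matching [count_matrix()] (same cells and genes).
#' @param ca a [detect_communities()] result aligned to the cells.
#' @return list of class `cluster_gene_stats` with matrices `mean_expr` and
#'   `pct_expressing` (clusters x genes, rownames are the 0-based cluster
#'   labels) and `cluster_sizes`.
#' @export
cluster_gene_stats <- function(nm, raw, ca) {
  stopifnot(inherits(nm, "normalized_matrix"), inherits(raw, "count_matrix"),
            inherits(ca, "cluster_assignment"),
            nrow(nm$values) == length(ca$labels),
            all(dim(nm$values) == dim(raw$counts)))
  f <- factor(ca$labels, levels = sort(unique(ca$labels)))
  ind <- Matrix::sparseMatrix(i = as.integer(f), j = seq_along(f), x = 1,
                              dims = c(nlevels(f), length(f)))
  sizes <- as.integer(table(f))
  mean_expr <- as.matrix(ind %*% nm$values) / sizes
  pct <- as.matrix(ind %*% (raw$counts > 0)) / sizes
  dimnames(mean_expr) <- dimnames(pct) <-
    list(levels(f), colnames(nm$values))
  structure(list(mean_expr = mean_expr, pct_expressing = pct,
                 cluster_sizes = stats::setNames(sizes, levels(f))),
            class = "cluster_gene_stats")
}

# Two-sided rank-sum p for x[mask] vs x[!mask]. Exact permutation
# enumeration when both group sizes are <= 8, tie-corrected normal
# approximation with continuity correction otherwise.
wilcox_rank_sum <- function(x, mask) {
  n1 <- sum(mask); n2 <- sum(!mask); n <- n1 + n2
  stopifnot(n1 >= 1, n2 >= 1)
  r <- rank(x)
  W <- sum(r[mask])
  mu <- n1 * (n + 1) / 2
  direction <- sign(W - mu)
  if (max(n1, n2) <= 8) {
    Wall <- utils::combn(n, n1, FUN = function(i) sum(r[i]))
    p <- mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
    return(list(p = p, direction = direction, statistic = W))
  }
  t <- rle(sort(x))$lengths
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(p = 1, direction = 0, statistic = W))
  z <- max(abs(W - mu) - 0.5, 0) / sqrt(sigma2)
  list(p = min(2 * stats::pnorm(-z), 1), direction = direction,
       statistic = W)
}

#' One-vs-rest Wilcoxon rank-sum test for a gene in a cluster
#'
#' Compares the normalized expression of a gene in all cells of a cluster
#' against all cells outside it. Uses exact permutation enumeration when
#' both group sizes are at most 8, and the tie-corrected normal
#' approximation (with continuity correction) for larger groups. All values
#' tied across both groups gives p = 1.
#'
#' @param nm a [normalize_log()] result.
#' @param ca a [detect_communities()] result.
#' @param cluster 0-based cluster label.
#' @param gene gene id or column index.
#' @return list with `p` (two-sided), `direction` (+1 if the cluster's rank
#'   sum exceeds its null expectation, -1 below, 0 tied) and `statistic`
#'   (the in-cluster rank sum).
#' @export
wilcoxon_one_vs_rest <- function(nm, ca, cluster, gene) {
  stopifnot(inherits(nm, "normalized_matrix"),
            inherits(ca, "cluster_assignment"))
  x <- as.numeric(nm$values[, gene])
  mask <- ca$labels == cluster
  if (!any(mask) || all(mask)) stop("cluster and its complement must be non-empty")
  wilcox_rank_sum(x, mask)
}

# Vectorized one-vs-rest tie-corrected normal Wilcoxon over all genes
# (columns of a dense matrix) for a fixed in-group mask.
wilcox_all_genes <- function(vals, mask) {
  n1 <- sum(mask); n2 <- sum(!mask); n <- n1 + n2
  G <- ncol(vals)
  p <- numeric(G); dir <- numeric(G)
  mu <- n1 * (n + 1) / 2
  if (max(n1, n2) <= 8) {  # exact enumeration regime
    for (g in seq_len(G)) {
      r <- wilcox_rank_sum(vals[, g], mask)
      p[g] <- r$p; dir[g] <- r$direction
    }
    return(list(p = p, direction = dir))
  }
  for (g in seq_len(G)) {
    x <- vals[, g]
    r <- rank(x)
    W <- sum(r[mask])
    t <- rle(sort(x))$lengths
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(t^3 - t) / (n * (n - 1)))
    if (sigma2 <= 0) { p[g] <- 1; dir[g] <- 0; next }
    z <- max(abs(W - mu) - 0.5, 0) / sqrt(sigma2)
    p[g] <- min(2 * stats::pnorm(-z), 1)
    dir[g] <- sign(W - mu)
  }
  list(p = p, direction = dir)
}

# Ratio scores for all genes with respect to one Treg cluster.
# Returns data.frame(score, infinite_like).
ratio_scores_all <- function(stats, cluster) {
  M <- stats$mean_expr
  ci <- match(as.character(cluster), rownames(M))
  if (is.na(ci)) stop("unknown cluster label: ", cluster)
  mc <- M[ci, ]
  second <- apply(M[-ci, , drop = FALSE], 2, max)
  eps <- if (any(M > 0)) min(M[M > 0]) else 1
  score <- numeric(ncol(M))
  infl <- logical(ncol(M))
  top <- mc > second  # strict unique maximum
  score[top & second > 0] <- mc[top & second > 0] / second[top & second > 0]
  inf_idx <- top & second == 0
  score[inf_idx] <- mc[inf_idx] / eps
  infl[inf_idx] <- TRUE
  data.frame(gene = colnames(M), score = score, infinite_like = infl,
             stringsAsFactors = FALSE)
}

#' Mean-expression-ratio marker score
#'
#' The bespoke marker statistic of the study: for a gene, clusters are
#' ordered by mean (normalized log) expression. If the designated Treg
#' cluster is not the strict unique top cluster, the score is 0; otherwise
#' it is the ratio of the Treg cluster's mean to the second-highest
#' cluster's mean. When the second-highest mean is zero the score is the
#' Treg mean divided by the smallest positive mean in the table and is
#' flagged "infinite-like" (attribute `infinite_like`), which preserves the
#' ranking without special-casing downstream sorts.
#'
#' @param stats a [cluster_gene_stats()] result (>= 2 clusters).
#' @param cluster 0-based label of the designated Treg cluster.
#' @param gene gene id or column index.
#' @return the score (0, or >= 1), with logical attribute `infinite_like`.
#' @export
marker_ratio_score <- function(stats, cluster, gene) {
  stopifnot(inherits(stats, "cluster_gene_stats"),
            nrow(stats$mean_expr) >= 2)
  M <- stats$mean_expr
  ci <- match(as.character(cluster), rownames(M))
  if (is.na(ci)) stop("unknown cluster label: ", cluster)
  mc <- M[ci, gene]
  second <- max(M[-ci, gene])
  if (!(mc > second)) return(structure(0, infinite_like = FALSE))
  if (second == 0) {
    eps <- if (any(M > 0)) min(M[M > 0]) else 1
    return(structure(unname(mc / eps), infinite_like = TRUE))
  }
  structure(unname(mc / second), infinite_like = FALSE)
}

#' Rank marker genes of a Treg cluster
#'
#' Computes, for every gene, the one-vs-rest Wilcoxon p-value
#' (Benjamini-Hochberg adjusted across genes within the cluster), the
#' mean-expression-ratio score, the log2 fold change of the cluster versus
#' the rest, and the percent of expressing cells inside and outside the
#' cluster. Genes with adjusted p at or below `p_threshold` and a positive
#' ratio score are returned ordered by decreasing score (ties broken by
#' gene id).
#'
#' The log2 fold change follows the convention of upstream rank-genes
#' statistics: `log2((expm1(mean log-expression in cluster) + 1e-9) /
#' (expm1(mean log-expression in rest) + 1e-9))`.
#'
#' @param nm a [normalize_log()] result.
#' @param raw the matching [count_matrix()].
#' @param ca a [detect_communities()] result.
#' @param cluster 0-based label of the Treg cluster.
#' @param top_n maximum number of markers returned (default all).
#' @param p_threshold cutoff on the BH-adjusted Wilcoxon p.
#' @return data.frame with columns gene, cluster, p_wilcoxon, padj,
#'   ratio_score, infinite_like, lfc, pct_in, pct_rest; zero rows allowed.
#' @export
rank_markers <- function(nm, raw, ca, cluster, top_n = Inf,
                         p_threshold = 0.05) {
  stats <- cluster_gene_stats(nm, raw, ca)
  rank_markers_from_stats(nm, raw, ca, stats, cluster, top_n, p_threshold)
}

# Same as rank_markers but reusing precomputed cluster_gene_stats.
rank_markers_from_stats <- function(nm, raw, ca, stats, cluster,
                                    top_n = Inf, p_threshold = 0.05) {
  cluster <- unname(cluster)
  mask <- ca$labels == cluster
  vals <- as.matrix(nm$values)
  wt <- wilcox_all_genes(vals, mask)
  padj <- bh_adjust(wt$p)
  sc <- ratio_scores_all(stats, cluster)
  eps <- 1e-9
  mean_in <- colMeans(vals[mask, , drop = FALSE])
  mean_rest <- colMeans(vals[!mask, , drop = FALSE])
  lfc <- unname(log2((expm1(mean_in) + eps) / (expm1(mean_rest) + eps)))
  ci <- match(as.character(cluster), rownames(stats$pct_expressing))
  sizes <- stats$cluster_sizes
  pct_in <- stats$pct_expressing[ci, ]
  pct_rest <- colSums(stats$pct_expressing[-ci, , drop = FALSE] *
                        sizes[-ci]) / sum(sizes[-ci])
  res <- data.frame(gene = sc$gene, cluster = cluster, p_wilcoxon = wt$p,
                    padj = padj, ratio_score = sc$score,
                    infinite_like = sc$infinite_like, lfc = lfc,
                    pct_in = unname(pct_in), pct_rest = unname(pct_rest),
                    stringsAsFactors = FALSE)
  res <- res[res$padj <= p_threshold & res$ratio_score > 0, , drop = FALSE]
  res <- res[order(-res$ratio_score, res$gene), , drop = FALSE]
  if (is.finite(top_n)) res <- utils::head(res, top_n)
  rownames(res) <- NULL
  res
}

#' Configuration for FOXP3-positive cluster calling
#'
#' @param foxp3_gene identifier of the FOXP3 gene.
#' @param pct_threshold minimum fraction of expressing cells in a called
#'   cluster (the study narrative places non-Treg clusters below 10%).
#' @param p_threshold cutoff on the BH-adjusted (across clusters)
#'   one-vs-rest Wilcoxon p.
#' @return list of class `foxp3_call_config`.
#' @export
foxp3_call_config <- function(foxp3_gene = "FOXP3", pct_threshold = 0.10,
                              p_threshold = 0.05) {
  stopifnot(pct_threshold > 0, pct_threshold < 1, p_threshold > 0)
  structure(list(foxp3_gene = foxp3_gene, pct_threshold = pct_threshold,
                 p_threshold = p_threshold), class = "foxp3_call_config")
}

#' Identify FOXP3-positive (Treg) clusters
#'
#' A cluster is called iff (a) the one-vs-rest Wilcoxon test on FOXP3 is
#' significant at `p_threshold` (BH-adjusted across clusters) with positive
#' direction, and (b) the fraction of cells expressing FOXP3 (raw count >
#' 0) is at least `pct_threshold`.
#'
#' @param nm a [normalize_log()] result.
#' @param raw the matching [count_matrix()].
#' @param ca a [detect_communities()] result.
#' @param cfg a [foxp3_call_config()].
#' @return list with `clusters` (integer vector of called 0-based labels)
#'   and `evidence` (data.frame per cluster: mean expression, percent
#'   expressing, p, padj, direction, called flag).
#' @export
identify_foxp3_clusters <- function(nm, raw, ca, cfg = foxp3_call_config()) {
  stopifnot(inherits(cfg, "foxp3_call_config"))
  if (!cfg$foxp3_gene %in% colnames(nm$values))
    stop("gene '", cfg$foxp3_gene, "' is not in the matrix; if it was ",
         "removed by gene filtering, whitelist it at the filtering step")
  x <- as.numeric(nm$values[, cfg$foxp3_gene])
  xraw <- as.numeric(raw$counts[, cfg$foxp3_gene])
  labs <- sort(unique(ca$labels))
  ev <- do.call(rbind, lapply(labs, function(cl) {
    mask <- ca$labels == cl
    wt <- wilcox_rank_sum(x, mask)
    data.frame(cluster = cl, mean_expr = mean(x[mask]),
               pct_expressing = mean(xraw[mask] > 0), p = wt$p,
               direction = wt$direction)
  }))
  ev$padj <- bh_adjust(ev$p)
  ev$called <- ev$padj <= cfg$p_threshold & ev$direction > 0 &
    ev$pct_expressing >= cfg$pct_threshold
  list(clusters = ev$cluster[ev$called], evidence = ev)
}
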