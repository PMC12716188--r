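#' Library-size normalization and log transform
#'
#' Scales every cell to `scale_target` total counts (default: the median of
#' the per-cell totals, a common upstream default) and applies `log(1 + x)`.
#' Zero counts map to zero, so sparsity is preserved.
#'
#' @param m a [count_matrix()].
#' @param scale_target per-cell count target on the linear scale; `NULL`
#'   uses the median total count.
#' @return list of class `normalized_matrix` with `values` (sparse cells x
#'   genes matrix of normalized log expression) and `scale_target`.
#' @export
normalize_log <- function(m, scale_target = NULL) {
  stopifnot(inherits(m, "count_matrix"), nrow(m$counts) > 0)
  tot <- Matrix::rowSums(m$counts)
  if (any(tot == 0))
    stop("cell(s) with zero total counts cannot be normalized: ",
         paste(utils::head(m$cell_ids[tot == 0], 3), collapse = ", "))
  if (is.null(scale_target)) scale_target <- stats::median(tot)
  v <- Matrix::Diagonal(x = scale_target / tot) %*% m$counts
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(m$counts)
  structure(list(values = v, scale_target = scale_target),
            class = "normalized_matrix")
}

#' Select highly variable genes
#'
#' Ranks genes by a dispersion statistic on the normalized log scale:
#' variance/mean, standardized within 20 equal-frequency mean bins (so that
#' the mean-dispersion trend does not dominate), ties broken by gene index.
#' Constant genes have zero dispersion and are never selected while any
#' non-constant gene remains.
#'
#' @param nm a [normalize_log()] result.
#' @param n_top number of genes to select (<= number of genes).
#' @param n_bins number of equal-frequency mean bins.
#' @return integer vector of selected gene column indices, named by gene id,
#'   in rank order.
#' @export
select_hvg <- function(nm, n_top = 1000, n_bins = 20) {
  stopifnot(inherits(nm, "normalized_matrix"))
  v <- nm$values
  G <- ncol(v)
  if (n_top > G) stop("n_top exceeds the number of genes")
  mu <- Matrix::colMeans(v)
  ex2 <- Matrix::colMeans(v^2)
  n <- nrow(v)
  vr <- pmax((ex2 - mu^2) * n / max(n - 1, 1), 0)
  # guard against cancellation residue for (near-)constant genes
  vr[vr < 1e-10 * (mu + 1)^2] <- 0
  d <- ifelse(mu > 0, vr / mu, 0)
  n_bins <- min(n_bins, G)
  bins <- cut(rank(mu, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  z <- d
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(d[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (d[i] - mean(d[i])) / s
  }
  z[vr == 0] <- -Inf  # constant genes rank last
  sel <- order(-z, seq_len(G))[seq_len(n_top)]
  stats::setNames(sel, colnames(v)[sel])
}

#' Principal-component embedding
#'
#' Per-gene centered PCA via eigendecomposition of the gene-gene covariance.
#' Components are ordered by decreasing variance and the sign convention
#' fixes the largest-magnitude loading of each component to be positive. If
#' the matrix has rank below `n_components`, the available components are
#' returned with a warning.
#'
#' @param x a `normalized_matrix`, or a numeric matrix (cells x genes),
#'   typically restricted to highly variable genes.
#' @param n_components number of components requested.
#' @return list of class `sc_embedding` with `coords` (cells x components),
#'   `n_components`, and `variance_explained` (per-component fraction of
#'   total variance).
#' @export
pca_embed <- function(x, n_components = 50) {
  if (inherits(x, "normalized_matrix")) x <- x$values
  x <- as.matrix(x)
  if (n_components > min(dim(x)))
    stop("n_components must be <= min(cells, genes)")
  x <- sweep(x, 2, colMeans(x))
  cv <- crossprod(x) / max(nrow(x) - 1, 1)
  e <- eigen(cv, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  tol <- max(ev) * 1e-10
  r <- sum(ev > tol)
  if (r < n_components) {
    warning(sprintf("rank %d below requested %d components; returning %d",
                    r, n_components, r))
    n_components <- r
  }
  v <- e$vectors[, seq_len(n_components), drop = FALSE]
  sgn <- apply(v, 2, function(u) {
    s <- sign(u[which.max(abs(u))]); if (s == 0) 1 else s
  })
  v <- sweep(v, 2, sgn, `*`)
  coords <- x %*% v
  rownames(coords) <- rownames(x)
  structure(list(coords = coords, n_components = n_components,
                 variance_explained = ev[seq_len(n_components)] / sum(ev),
                 rotation = v),
            class = "sc_embedding")
}

#' Batch correction by per-batch centering of the embedding
#'
#' For every batch and component, the batch mean is subtracted and the
#' global mean restored. This removes location-shift batch effects in the
#' embedding; single-batch input is returned unchanged.
#'
#' @param e an [pca_embed()] result.
#' @param batch per-cell batch labels (length = number of cells).
#' @return an `sc_embedding` with centered coordinates.
#' @export
center_batches <- function(e, batch) {
  stopifnot(inherits(e, "sc_embedding"),
            length(batch) == nrow(e$coords), !anyNA(batch))
  batch <- as.factor(batch)
  if (nlevels(batch) <= 1) return(e)
  coords <- e$coords
  gm <- colMeans(coords)
  for (b in levels(batch)) {
    i <- batch == b
    coords[i, ] <- sweep(coords[i, , drop = FALSE], 2,
                         colMeans(coords[i, , drop = FALSE]))
  }
  e$coords <- sweep(coords, 2, gm, `+`)
  e
}

#' Build a weighted k-nearest-neighbor graph
#'
#' Undirected graph over cells: the edge (i, j) is present iff j is among
#' i's k nearest neighbors (Euclidean distance in the embedding) or vice
#' versa. Distance ties are broken by cell index. Edge weights are a
#' Gaussian kernel with locally adaptive bandwidth,
#' `w_ij = exp(-d_ij^2 / (sigma_i * sigma_j))` with `sigma_i` the distance
#' from i to its k-th neighbor, so weights lie in (0, 1] and duplicate
#' coordinates receive weight 1.
#'
#' @param e an [pca_embed()] result or a numeric coordinate matrix.
#' @param k number of nearest neighbors (default 15, the common upstream
#'   default; must be < number of cells).
#' @return an `igraph` undirected graph with edge attribute `weight`; the
#'   neighbor index matrix is attached as graph attribute `knn_index`.
#' @export
build_knn_graph <- function(e, k = 15) {
  coords <- if (inherits(e, "sc_embedding")) e$coords else as.matrix(e)
  n <- nrow(coords)
  if (k >= n) stop("k must be < number of cells")
  rs <- rowSums(coords^2)
  nn_idx <- matrix(0L, n, k)
  nn_d2 <- matrix(0, n, k)
  bs <- 1024L
  for (s in seq(1, n, bs)) {
    en <- min(s + bs - 1L, n)
    d2 <- outer(rs[s:en], rs, `+`) -
      2 * tcrossprod(coords[s:en, , drop = FALSE], coords)
    for (i in seq_len(en - s + 1L)) {
      o <- order(d2[i, ], seq_len(n))[2:(k + 1)]
      nn_idx[s + i - 1L, ] <- o
      nn_d2[s + i - 1L, ] <- pmax(d2[i, o], 0)
    }
  }
  sig <- sqrt(pmax(nn_d2[, k], 1e-12))
  ii <- rep(seq_len(n), k)
  jj <- as.vector(nn_idx)
  w <- exp(-as.vector(nn_d2) / (sig[ii] * sig[jj]))
  a <- pmin(ii, jj); b <- pmax(ii, jj)
  o <- order(a, b)
  a <- a[o]; b <- b[o]; w <- w[o]
  first <- !duplicated(cbind(a, b))
  grpid <- cumsum(first)
  wmax <- tapply(w, grpid, max)
  g <- igraph::make_undirected_graph(rbind(a[first], b[first]), n = n)
  igraph::E(g)$weight <- as.numeric(wmax)
  g <- igraph::set_graph_attr(g, "knn_index", nn_idx)
  g
}

#' Graph community detection (Leiden)
#'
#' Partitions the neighbor graph by optimizing resolution-parameterized
#' modularity with the Leiden algorithm. The partition is seeded (so results
#' are reproducible) and labels are relabeled by decreasing cluster size,
#' 0-based, following the numbering convention of upstream single-cell
#' toolkits.
#'
#' @param graph an igraph graph (as from [build_knn_graph()]).
#' @param resolution resolution parameter (> 0); higher values give more,
#'   smaller clusters. The study used 1.5.
#' @param seed integer seed for the community detection.
#' @param n_iterations Leiden refinement iterations.
#' @return list of class `cluster_assignment` with `labels` (integer,
#'   0-based, dense), `resolution`, `n_clusters`.
#' @export
detect_communities <- function(graph, resolution = 1.5, seed = 0L,
                               n_iterations = 5) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  if (resolution <= 0) stop("resolution must be > 0")
  set.seed(seed)
  cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
                               weights = igraph::E(graph)$weight,
                               resolution = resolution,
                               n_iterations = n_iterations)
  memb <- as.integer(igraph::membership(cl))
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes)[ord])
  labels <- unname(relabel[as.character(memb)])
  structure(list(labels = as.integer(labels), resolution = resolution,
                 n_clusters = length(sizes)),
            class = "cluster_assignment")
}
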