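#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' the ratio of the sample's count to the gene's geometric mean across
#' samples. Reference genes are those with a nonzero count in every sample;
#' genes with any zero are excluded from the reference set. This is the
#' normalization the study applied to the bulk counts.
#'
#' @param counts genes x samples non-negative count matrix.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no reference genes (every gene has a zero count in some sample); ",
         "consider a pseudo-reference fallback such as adding a pseudocount ",
         "or using only high-count genes - not applied silently")
  lg <- log(counts[ref, , drop = FALSE])
  geo <- exp(rowMeans(lg))
  sf <- apply(counts[ref, , drop = FALSE] / geo, 2, stats::median)
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("non-finite size factor")
  sf
}

# OLS design-based fitted means of normalized counts (used by the
# method-of-moments dispersion estimator).
ols_fitted <- function(q, X) {
  pmax(drop(X %*% qr.coef(qr(X), q)), 1e-8)
}

#' Per-gene dispersion estimation
#'
#' Gene-wise method-of-moments on normalized counts with design-based
#' means: with `q = K/s`, `E(q - mu)^2 = mu/s + alpha mu^2` per sample, so
#' `alpha_hat = (RSS * n/(n-p) - sum(mu/s)) / sum(mu^2)`, floored at
#' `alpha_min`. With `moderate = TRUE` (the default used by the pipeline)
#' the gene-wise estimates are shrunk on the log scale toward a central
#' value, with shrinkage weight derived from the excess of the robust
#' spread of log gene-wise estimates over their theoretical sampling noise
#' (`trigamma((n-p)/2)`): when the gene-wise spread is consistent with pure
#' sampling noise the estimates collapse to the central value, and genuine
#' dispersion heterogeneity is preserved. This moderation is what makes the
#' downstream Wald test calibrated at small sample sizes.
#'
#' @param counts genes x samples count matrix.
#' @param sf per-sample size factors.
#' @param design model matrix (samples x coefficients).
#' @param moderate apply empirical-Bayes moderation (default TRUE).
#' @param alpha_min lower floor for the dispersion.
#' @return numeric vector of dispersions (one per gene), with the
#'   unmoderated gene-wise estimates in attribute `raw`.
#' @export
estimate_dispersions <- function(counts, sf, design, moderate = TRUE,
                                 alpha_min = 1e-8) {
  counts <- as.matrix(counts)
  n <- ncol(counts); p <- qr(design)$rank
  if (n < 3) stop("need at least 3 samples")
  q <- t(t(counts) / sf)
  H <- design %*% qr.solve(crossprod(design)) %*% t(design)
  muhat <- pmax(t(H %*% t(q)), 1e-8)  # genes x samples fitted means
  rss <- rowSums((q - muhat)^2) * n / (n - p)
  raw <- (rss - muhat %*% (1 / sf)) / rowSums(muhat^2)
  raw <- pmax(drop(raw), alpha_min)
  out <- raw
  if (moderate) {
    ok <- raw > 10 * alpha_min
    if (any(ok)) {
      la <- log(raw)
      ltr <- log(mean(raw[ok]))
      s_samp <- trigamma((n - p) / 2)
      s_prior <- max(stats::mad(la[ok], center = ltr)^2 - s_samp, 1e-4)
      w <- s_prior / (s_prior + s_samp)
      out <- pmax(exp(w * la + (1 - w) * ltr), alpha_min)
    }
  }
  names(out) <- rownames(counts)
  attr(out, "raw") <- stats::setNames(raw, rownames(counts))
  out
}

# NB log-likelihood with mean mu and dispersion alpha (variance mu+alpha*mu^2).
nb_loglik <- function(y, mu, alpha) {
  sum(stats::dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

#' Fit a negative-binomial GLM for one gene
#'
#' Maximizes the NB log-likelihood with log link and offset `log(sf)` by
#' iteratively reweighted least squares at fixed dispersion. Convergence is
#' declared when the largest coefficient update falls below `tol` (default
#' 1e-8) within `maxit` iterations; otherwise the fit is flagged
#' non-converged. The coefficient covariance is the inverse observed
#' information. All-zero genes are skipped and flagged.
#'
#' @param y integer counts for one gene (length = samples).
#' @param sf per-sample size factors.
#' @param X design model matrix (full column rank).
#' @param alpha dispersion (> 0).
#' @param tol,maxit IRLS convergence tolerance and iteration cap.
#' @return list of class `nb_fit`: `beta` (log-scale coefficients), `cov`
#'   (inverse observed information), `loglik`, `converged`, `skipped`,
#'   `alpha`, `X`, `mu` (fitted means), `iter`.
#' @export
fit_nb_glm <- function(y, sf, X, alpha, tol = 1e-8, maxit = 100) {
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("design matrix is not full column rank")
  stopifnot(length(y) == nrow(X), length(sf) == nrow(X), alpha > 0)
  if (all(y == 0)) {
    return(structure(list(beta = rep(NA_real_, ncol(X)), cov = NULL,
                          loglik = NA_real_, converged = FALSE,
                          skipped = TRUE, alpha = alpha, X = X,
                          mu = rep(0, length(y)), iter = 0L),
                     class = "nb_fit"))
  }
  off <- log(sf)
  q <- y / sf
  beta <- qr.coef(qr(X), log(q + 0.5))
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxit)) {
    iter <- it
    eta <- pmin(pmax(drop(X %*% beta) + off, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (y - mu) / mu
    XtW <- t(X * w)
    beta_new <- drop(solve(XtW %*% X, XtW %*% z))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  mu <- exp(pmin(pmax(drop(X %*% beta) + off, -30), 30))
  winfo <- mu * (1 + alpha * y) / (1 + alpha * mu)^2
  info <- t(X * winfo) %*% X
  covb <- tryCatch(solve(info), error = function(e) NULL)
  structure(list(beta = stats::setNames(beta, colnames(X)), cov = covb,
                 loglik = nb_loglik(y, mu, alpha), converged = converged,
                 skipped = FALSE, alpha = alpha, X = X, mu = mu,
                 iter = iter),
            class = "nb_fit")
}

#' Wald test of a coefficient contrast
#'
#' Tests `c' beta = 0`: the log2 fold change is `c' beta / ln 2`, the Wald
#' statistic `c' beta / SE(c' beta)` with the standard error from the
#' inverse observed information, and the p-value two-sided normal. A
#' non-converged or skipped fit yields NA results with `flagged = TRUE`.
#'
#' @param fit an [fit_nb_glm()] result.
#' @param contrast numeric contrast vector (length = number of
#'   coefficients).
#' @return list with `lfc`, `wald_stat`, `p_wald`, `flagged`.
#' @export
wald_contrast_test <- function(fit, contrast) {
  stopifnot(inherits(fit, "nb_fit"))
  if (fit$skipped || !fit$converged || is.null(fit$cov))
    return(list(lfc = NA_real_, wald_stat = NA_real_, p_wald = NA_real_,
                flagged = TRUE))
  stopifnot(length(contrast) == length(fit$beta))
  est <- sum(contrast * fit$beta)
  if (all(contrast == 0))
    return(list(lfc = 0, wald_stat = 0, p_wald = 1, flagged = FALSE))
  se <- sqrt(drop(t(contrast) %*% fit$cov %*% contrast))
  stat <- est / se
  list(lfc = est / log(2), wald_stat = stat,
       p_wald = 2 * stats::pnorm(-abs(stat)), flagged = FALSE)
}

#' Likelihood-ratio test of nested NB fits
#'
#' Compares a full and a reduced fit of the same gene at the same
#' dispersion: the statistic is `2 (loglik_full - loglik_reduced)` (clamped
#' at 0 against convergence round-off) and the p-value comes from a
#' chi-square with degrees of freedom equal to the rank difference of the
#' two designs. The reduced design must be nested in the full design.
#'
#' @param fit_full,fit_reduced [fit_nb_glm()] results for the same gene.
#' @return list with `lrt_stat`, `df`, `p_lrt`, `flagged`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "nb_fit"), inherits(fit_reduced, "nb_fit"))
  if (fit_full$skipped || fit_reduced$skipped ||
      !fit_full$converged || !fit_reduced$converged)
    return(list(lrt_stat = NA_real_, df = NA_integer_, p_lrt = NA_real_,
                flagged = TRUE))
  if (abs(fit_full$alpha - fit_reduced$alpha) > 1e-12)
    stop("full and reduced fits must use the same dispersion")
  Xf <- fit_full$X; Xr <- fit_reduced$X
  # nesting: every reduced column must lie in the column span of the full
  resid <- Xr - Xf %*% qr.coef(qr(Xf), Xr)
  if (max(abs(resid)) > 1e-8)
    stop("reduced design is not nested in the full design")
  df <- qr(Xf)$rank - qr(Xr)$rank
  stat <- max(2 * (fit_full$loglik - fit_reduced$loglik), 0)
  # identical designs (df = 0): no constraint tested, p = 1 by convention
  p <- if (df == 0) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  list(lrt_stat = stat, df = df, p_lrt = p, flagged = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement. NA p-values are propagated as
#' NA and excluded from the number of tests.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Z-score expression matrix across conditions
#'
#' Standardizes each gene's normalized condition means to zero mean and
#' unit (sample) standard deviation across conditions - the statistic shown
#' in the study's expression heatmap. Constant genes map to all zeros.
#'
#' @param cond_means genes x conditions matrix of normalized mean
#'   expression (>= 2 conditions).
#' @return matrix of the same shape with per-gene Z-scores.
#' @export
zscore_expression <- function(cond_means) {
  cond_means <- as.matrix(cond_means)
  if (ncol(cond_means) < 2) stop("need >= 2 conditions")
  mu <- rowMeans(cond_means)
  sd <- apply(cond_means, 1, stats::sd)
  z <- (cond_means - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Venn region partition of significant genes across three contrasts
#'
#' Splits the significant genes of three contrasts (at a padj cutoff, in
#' one direction) into the 7 Venn regions. Region counts sum to the size of
#' the union.
#'
#' @param results named list of 3 per-contrast result data.frames (each
#'   with columns `gene`, `padj`, `lfc`), sharing one gene universe.
#' @param padj_cutoff significance cutoff on the adjusted p-value.
#' @param direction `"up"` (lfc > 0) or `"down"` (lfc < 0).
#' @return list with `counts` (named integer vector over the 7 regions,
#'   names like `"A"`, `"A&B"`, `"A&B&C"` built from the contrast names)
#'   and `genes` (the corresponding gene lists).
#' @export
contrast_overlap_sets <- function(results, padj_cutoff = 0.05,
                                  direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(length(results) == 3, !is.null(names(results)))
  uni <- results[[1]]$gene
  for (r in results) {
    if (!identical(sort(r$gene), sort(uni)))
      stop("contrasts must share the same gene universe")
  }
  sig <- lapply(results, function(r) {
    keep <- !is.na(r$padj) & r$padj <= padj_cutoff &
      if (direction == "up") r$lfc > 0 else r$lfc < 0
    r$gene[keep]
  })
  nm <- names(results)
  member <- sapply(sig, function(s) uni %in% s)  # genes x 3 logical
  counts <- integer(0); genes <- list()
  for (pattern in 1:7) {
    bits <- as.logical(bitwAnd(pattern, c(1, 2, 4)))
    region <- paste(nm[bits], collapse = "&")
    inreg <- rowSums(member == rep(bits, each = length(uni))) == 3
    genes[[region]] <- uni[inreg]
    counts[region] <- sum(inreg)
  }
  list(counts = counts, genes = genes)
}

#' Negative-binomial differential expression for the CD25 design
#'
#' Full engine run: median-of-ratios size factors, moderated gene-wise
#' dispersions, NB GLM fits of the full (`~ sex + cd25_group`) and reduced
#' (`~ sex`) models, Wald tests for the three pairwise CD25 contrasts
#' (high vs negative, low vs negative, high vs low), the design-level
#' likelihood-ratio test, and BH adjustment within each contrast.
#'
#' @param counts genes x samples count matrix.
#' @param meta data.frame with columns `sample`, `sex` (`F`/`M`) and
#'   `cd25_group` (`negative`/`low`/`high`), matching the count columns.
#' @param p_threshold padj cutoff stored alongside (used by downstream
#'   Venn summaries).
#' @param moderate_dispersion passed to [estimate_dispersions()].
#' @return list of class `bulk_de_result`: `results` (named list of
#'   per-contrast data.frames: gene, base_mean, lfc, wald_stat, p_wald,
#'   p_lrt, padj, padj_lrt, flagged), `size_factors`, `dispersions`,
#'   `design`, `cond_means` (genes x 3 normalized group means), `meta`.
#' @export
bulk_de <- function(counts, meta, p_threshold = 0.05,
                    moderate_dispersion = TRUE) {
  counts <- as.matrix(counts)
  if (!all(c("sample", "sex", "cd25_group") %in% names(meta)))
    stop("metadata needs columns sample, sex, cd25_group")
  missing_meta <- setdiff(colnames(counts), meta$sample)
  missing_counts <- setdiff(meta$sample, colnames(counts))
  if (length(missing_meta) || length(missing_counts))
    stop("sample mismatch between counts and metadata: ",
         paste(c(missing_meta, missing_counts), collapse = ", "))
  meta <- meta[match(colnames(counts), meta$sample), ]
  grp <- factor(meta$cd25_group, levels = c("negative", "low", "high"))
  sex <- factor(meta$sex)
  if (any(table(grp) < 2)) stop("need >= 2 samples per cd25_group")
  X <- stats::model.matrix(~ sex + grp)
  Xr <- stats::model.matrix(~ sex)
  colnames(X) <- sub("^grp", "cd25", colnames(X))
  sf <- size_factors_median_of_ratios(counts)
  alphas <- estimate_dispersions(counts, sf, X,
                                 moderate = moderate_dispersion)
  q <- t(t(counts) / sf)
  base_mean <- rowMeans(q)
  cond_means <- sapply(levels(grp), function(g)
    rowMeans(q[, grp == g, drop = FALSE]))
  contrasts <- list(
    high_vs_negative = as.numeric(colnames(X) == "cd25high"),
    low_vs_negative = as.numeric(colnames(X) == "cd25low"),
    high_vs_low = as.numeric(colnames(X) == "cd25high") -
      as.numeric(colnames(X) == "cd25low"))
  G <- nrow(counts)
  out <- lapply(contrasts, function(cv)
    data.frame(gene = rownames(counts), base_mean = base_mean,
               lfc = NA_real_, wald_stat = NA_real_, p_wald = NA_real_,
               p_lrt = NA_real_, flagged = FALSE,
               stringsAsFactors = FALSE, row.names = NULL))
  for (g in seq_len(G)) {
    ff <- fit_nb_glm(counts[g, ], sf, X, alphas[g])
    fr <- fit_nb_glm(counts[g, ], sf, Xr, alphas[g])
    lrt <- likelihood_ratio_test(ff, fr)
    for (cn in names(contrasts)) {
      wt <- wald_contrast_test(ff, contrasts[[cn]])
      out[[cn]]$lfc[g] <- wt$lfc
      out[[cn]]$wald_stat[g] <- wt$wald_stat
      out[[cn]]$p_wald[g] <- wt$p_wald
      out[[cn]]$p_lrt[g] <- lrt$p_lrt
      out[[cn]]$flagged[g] <- wt$flagged || lrt$flagged
    }
  }
  for (cn in names(out)) {
    out[[cn]]$padj <- bh_adjust(out[[cn]]$p_wald)
    out[[cn]]$padj_lrt <- bh_adjust(out[[cn]]$p_lrt)
  }
  structure(list(results = out, size_factors = sf, dispersions = alphas,
                 design = X, cond_means = cond_means, meta = meta,
                 p_threshold = p_threshold),
            class = "bulk_de_result")
}
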