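test_that("median-of-ratios size factors: hand case, identity, oracle", {
  counts <- cbind(A = 2 * c(1, 2, 4), B = c(1, 2, 4))
  sf <- size_factors_median_of_ratios(counts)
  expect_equal(unname(sf), c(sqrt(2), 1 / sqrt(2)), tolerance = 1e-12)

  same <- matrix(rep(c(3, 7, 11), 4), 3, 4)
  expect_equal(unname(size_factors_median_of_ratios(same)), rep(1, 4))

  zeroy <- rbind(c(0, 5, 5), c(5, 0, 5), c(5, 5, 0))
  expect_error(size_factors_median_of_ratios(zeroy), "pseudo-reference")

  oracle <- function(m) {
    ref <- apply(m, 1, function(r) all(r > 0))
    geo <- exp(rowMeans(log(m[ref, , drop = FALSE])))
    apply(m[ref, , drop = FALSE], 2, function(col)
      stats::median(col / geo))
  }
  set.seed(31)
  for (i in 1:10) {
    m <- matrix(rnbinom(200 * 6, mu = 50, size = 5), 200, 6)
    expect_equal(unname(size_factors_median_of_ratios(m)),
                 unname(oracle(m)), tolerance = 1e-12)
  }
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(32)
  m <- matrix(rnbinom(300 * 8, mu = 80, size = 4), 300, 8)
  ours <- size_factors_median_of_ratios(m)
  ref <- suppressMessages(DESeq2::estimateSizeFactorsForMatrix(m))
  # DESeq2 interpolates the median on the log scale; with an even number
  # of reference genes the two conventions differ only in the fourth digit
  expect_equal(unname(ours), unname(ref), tolerance = 1e-3)
})

test_that("dispersion estimation recovers the simulation truth", {
  set.seed(33)
  n <- 12
  grp <- factor(rep(c("n", "l", "h"), each = 4), levels = c("n", "l", "h"))
  X <- stats::model.matrix(~ grp)
  sf <- rep(1, n)

  pois <- t(sapply(1:1000, function(i)
    rpois(n, lambda = runif(1, 50, 500))))
  a_pois <- attr(estimate_dispersions(pois, sf, X), "raw")
  expect_lte(median(a_pois), 0.01)

  nb <- t(sapply(1:2000, function(i)
    rnbinom(n, mu = runif(1, 50, 500), size = 1 / 0.5)))
  a_nb <- attr(estimate_dispersions(nb, sf, X), "raw")
  expect_gte(median(a_nb), 0.3)
  expect_lte(median(a_nb), 0.7)

  const <- matrix(40, 2, n)
  a_const <- estimate_dispersions(const, sf, X, moderate = FALSE)
  expect_equal(unname(a_const), rep(1e-8, 2), ignore_attr = TRUE)
})

test_that("NB GLM fit honors Poisson-limit closed forms", {
  set.seed(34)
  n <- 8
  X <- cbind(1, rep(0:1, each = 4))
  sf <- rep(1, n)
  y <- c(rpois(4, 40), rpois(4, 160))
  f <- fit_nb_glm(y, sf, X, alpha = 1e-8)
  expect_true(f$converged)
  expect_equal(exp(f$beta[2]), mean(y[5:8]) / mean(y[1:4]),
               tolerance = 1e-6, ignore_attr = TRUE)

  # intercept-only: fitted mean is the size-factor-weighted mean
  sf2 <- c(0.5, 1, 1.5, 2, 0.8, 1.2, 1, 1)
  f0 <- fit_nb_glm(y, sf2, matrix(1, n, 1), alpha = 1e-8)
  expect_equal(exp(f0$beta[1]), sum(y) / sum(sf2), tolerance = 1e-6,
               ignore_attr = TRUE)

  expect_error(fit_nb_glm(y, sf, cbind(X, X[, 2]), 0.1), "full column rank")
  fz <- fit_nb_glm(rep(0, n), sf, X, 0.1)
  expect_true(fz$skipped)
})

test_that("Wald contrast behaves at the null vector and flags bad fits", {
  set.seed(35)
  X <- cbind(1, rep(0:1, each = 4))
  y <- rnbinom(8, mu = 100, size = 10)
  f <- fit_nb_glm(y, rep(1, 8), X, 0.1)
  w0 <- wald_contrast_test(f, c(0, 0))
  expect_equal(w0$lfc, 0)
  expect_equal(w0$p_wald, 1)

  fbad <- fit_nb_glm(y, rep(1, 8), X, 0.1, maxit = 1)
  expect_false(fbad$converged)
  wb <- wald_contrast_test(fbad, c(0, 1))
  expect_true(wb$flagged)
  expect_true(is.na(wb$p_wald))
})

test_that("likelihood-ratio test: nesting, degenerate df, non-negativity", {
  set.seed(36)
  n <- 12
  grp <- factor(rep(c("n", "l", "h"), each = 4), levels = c("n", "l", "h"))
  sex <- factor(rep(c("F", "M"), 6))
  Xf <- stats::model.matrix(~ sex + grp)
  Xr <- stats::model.matrix(~ sex)
  sf <- rep(1, n)

  y <- rnbinom(n, mu = 100, size = 10)
  ff <- fit_nb_glm(y, sf, Xf, 0.1)
  fr <- fit_nb_glm(y, sf, Xf, 0.1)
  same <- likelihood_ratio_test(ff, fr)
  expect_equal(same$lrt_stat, 0, tolerance = 1e-8)
  expect_equal(same$p_lrt, 1)

  # non-nested reduced design errors
  Xother <- cbind(1, rnorm(n))
  fo <- fit_nb_glm(y, sf, Xother, 0.1)
  expect_error(likelihood_ratio_test(ff, fo), "nested")

  # mismatched dispersions error
  fr2 <- fit_nb_glm(y, sf, Xr, 0.2)
  expect_error(likelihood_ratio_test(ff, fr2), "same dispersion")

  # statistic is never negative across simulated genes, df = 2
  stats_ok <- TRUE
  for (g in 1:100) {
    yy <- rnbinom(n, mu = runif(1, 20, 500), size = 10)
    f1 <- fit_nb_glm(yy, sf, Xf, 0.1)
    f2 <- fit_nb_glm(yy, sf, Xr, 0.1)
    l <- likelihood_ratio_test(f1, f2)
    stats_ok <- stats_ok && l$lrt_stat >= 0 && l$df == 2
  }
  expect_true(stats_ok)
})

test_that("BH adjustment matches the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # NA propagation: NAs do not count toward the number of tests
  expect_equal(bh_adjust(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Z-scores standardize per gene across conditions", {
  z <- zscore_expression(rbind(c(1, 2, 3), c(5, 5, 5)))
  expect_equal(unname(z[1, ]), c(-1, 0, 1))
  expect_equal(unname(z[2, ]), c(0, 0, 0))
  set.seed(37)
  zz <- zscore_expression(matrix(runif(60), 20, 3))
  expect_lt(max(abs(rowSums(zz))), 1e-10)
  expect_error(zscore_expression(matrix(1, 3, 1)), "conditions")
})

test_that("Venn regions partition significant genes correctly", {
  mk <- function(genes, sig_up) {
    data.frame(gene = genes, padj = ifelse(genes %in% sig_up, 0.01, 0.9),
               lfc = ifelse(genes %in% sig_up, 1, 0.1))
  }
  uni <- sprintf("g%02d", 1:20)
  res <- list(A = mk(uni, c("g01", "g02", "g03", "g04", "g05")),
              B = mk(uni, c("g04", "g05", "g06", "g07")),
              C = mk(uni, c("g05", "g07", "g20")))
  v <- contrast_overlap_sets(res, 0.05, "up")
  # brute-force set algebra
  expect_equal(unname(v$counts["A"]), 3L)          # g01 g02 g03
  expect_equal(unname(v$counts["A&B"]), 1L)        # g04
  expect_equal(unname(v$counts["A&B&C"]), 1L)      # g05
  expect_equal(unname(v$counts["B&C"]), 1L)        # g07
  expect_equal(unname(v$counts["C"]), 1L)          # g20
  expect_equal(unname(v$counts["B"]), 1L)          # g06
  expect_equal(unname(v$counts["A&C"]), 0L)
  expect_equal(sum(v$counts), length(Reduce(union, lapply(res, function(r)
    r$gene[r$padj <= 0.05 & r$lfc > 0]))))

  # disjoint sets populate only singleton regions
  res2 <- list(A = mk(uni, "g01"), B = mk(uni, "g02"), C = mk(uni, "g03"))
  v2 <- contrast_overlap_sets(res2, 0.05, "up")
  expect_equal(unname(v2$counts[c("A&B", "A&C", "B&C", "A&B&C")]),
               rep(0L, 4))
  # identical sets populate only the triple intersection
  res3 <- list(A = mk(uni, c("g01", "g02")), B = mk(uni, c("g01", "g02")),
               C = mk(uni, c("g01", "g02")))
  v3 <- contrast_overlap_sets(res3, 0.05, "up")
  expect_equal(unname(v3$counts["A&B&C"]), 2L)
  expect_equal(sum(v3$counts), 2L)
})

test_that("normalization removes planted library-size effects", {
  bulk <- simulate_bulk_dataset(bulk_sim_config(n_genes = 1500, seed = 38))
  sf <- size_factors_median_of_ratios(bulk$counts)
  # estimated factors track the planted ones
  expect_gt(cor(log(sf), log(bulk$size_factors)), 0.95)
  q <- t(t(bulk$counts) / sf)
  gm <- sapply(split(seq_len(12), bulk$meta$cd25_group),
               function(j) mean(q[, j]))
  expect_lt(max(gm) / min(gm), 1.05)
})

test_that("Wald and LRT p-values rank together on alternatives", {
  ge <- matrix(0, 600, 2)
  set.seed(39)
  ge[, 2] <- runif(600, 0.3, 2.5) * sample(c(-1, 1), 600, replace = TRUE)
  bulk <- simulate_bulk_dataset(bulk_sim_config(n_genes = 600,
                                                group_effects = ge,
                                                seed = 39))
  de <- bulk_de(bulk$counts, bulk$meta)
  r <- de$results$high_vs_negative
  expect_gt(cor(r$p_wald, r$p_lrt, method = "spearman", use = "complete.obs"),
            0.9)
  # padj invariants
  expect_true(all(r$padj >= r$p_wald - 1e-15, na.rm = TRUE))
  expect_true(all(r$padj <= 1, na.rm = TRUE))
  o <- order(r$p_wald)
  expect_true(all(diff(r$padj[o]) >= -1e-15, na.rm = TRUE))
})

test_that("the full engine recovers planted effects with controlled FDR", {
  ge <- matrix(0, 2000, 2)
  ge[1:100, 2] <- 2
  ge[101:200, 2] <- -2
  bulk <- simulate_bulk_dataset(bulk_sim_config(n_genes = 2000,
                                                group_effects = ge,
                                                sex_effect = rep(c(0.5, 0),
                                                                 c(200, 1800)),
                                                seed = 40))
  de <- bulk_de(bulk$counts, bulk$meta)
  r <- de$results$high_vs_negative
  sig <- which(!is.na(r$padj) & r$padj < 0.05)
  sens <- mean(1:200 %in% sig)
  fdr <- sum(!(sig %in% 1:200)) / max(1, length(sig))
  expect_gte(sens, 0.7)
  expect_lte(fdr, 0.1)
})

test_that("the engine agrees with DESeq2 on effect ranking", {
  ge <- matrix(0, 300, 2)
  set.seed(41)
  ge[1:150, 2] <- runif(150, -2, 2)
  bulk <- simulate_bulk_dataset(bulk_sim_config(n_genes = 300,
                                                group_effects = ge,
                                                seed = 41))
  de <- bulk_de(bulk$counts, bulk$meta)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      bulk$counts,
      S4Vectors::DataFrame(sex = factor(bulk$meta$sex),
                           cd25 = factor(bulk$meta$cd25_group,
                                         levels = c("negative", "low",
                                                    "high"))),
      design = ~ sex + cd25)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds, contrast = c("cd25", "high", "negative"))
  })
  ours <- de$results$high_vs_negative
  expect_gt(cor(ours$lfc, ref$log2FoldChange, use = "complete.obs"), 0.95)
  expect_gt(cor(rank(ours$p_wald), rank(ref$pvalue),
                use = "complete.obs"), 0.9)
})
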