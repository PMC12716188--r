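#!/usr/bin/env Rscript
# Bulk stage: median-of-ratios normalization, moderated NB dispersions,
# NB GLM fits (~ sex + CD25 vs ~ sex), Wald contrasts, LRT, BH adjustment,
# Z-score matrix and Venn partition; checked against the planted truth.

suppressPackageStartupMessages(library(tregsig))

data_dir <- "scratch/data/bulk"
run_dir <- "scratch/runs/bulk"
res_dir <- "results/bulk"
dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

de <- run_bulk_pipeline(file.path(data_dir, "counts.csv"),
                        file.path(data_dir, "metadata.tsv"), run_dir)

truth <- utils::read.table(file.path(data_dir, "truth_lfc.tsv"),
                           header = TRUE, sep = "\t")
r <- de$results$high_vs_negative
planted <- which(truth$high != 0)
sig <- which(!is.na(r$padj) & r$padj < 0.05)
sens <- mean(planted %in% sig)
fdr <- if (length(sig)) sum(!(sig %in% planted)) / length(sig) else 0
mae <- stats::median(abs(r$lfc[planted] - truth$high[planted]))

message(sprintf("high vs negative: %d significant at padj < 0.05 (of %d genes)",
                length(sig), nrow(r)))
message(sprintf("  sensitivity %.3f, observed FDR %.3f, median |LFC error| %.3f",
                sens, fdr, mae))
for (cn in names(de$results)) {
  rr <- de$results[[cn]]
  message(sprintf("  %-18s %4d up / %4d down (padj < 0.05)", cn,
                  sum(rr$padj < 0.05 & rr$lfc > 0, na.rm = TRUE),
                  sum(rr$padj < 0.05 & rr$lfc < 0, na.rm = TRUE)))
}

# compact per-contrast summaries: top 50 genes by padj
for (cn in names(de$results)) {
  rr <- de$results[[cn]]
  top <- utils::head(rr[order(rr$padj), ], 50)
  top[-1] <- lapply(top[-1], function(x)
    if (is.numeric(x)) signif(x, 6) else x)
  utils::write.table(top, file.path(res_dir, sprintf("top50_%s.tsv", cn)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
for (f in c("size_factors.tsv", "venn.json", "run_log.json"))
  file.copy(file.path(run_dir, f), file.path(res_dir, f), overwrite = TRUE)
summ <- data.frame(contrast = "high_vs_negative", n_sig = length(sig),
                   sensitivity = round(sens, 4), fdr = round(fdr, 4),
                   median_abs_lfc_error = round(mae, 4))
utils::write.table(summ, file.path(res_dir, "summary.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("summaries written to ", res_dir)
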