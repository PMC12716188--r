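#!/usr/bin/env Rscript
# qPCR stage: delta-CT against the reference gene, delta-delta-CT fold
# changes against the CD25-negative gate, one-way ANOVA + Tukey HSD.

suppressPackageStartupMessages(library(tregsig))

data_dir <- "scratch/data"
res_dir <- "results/qpcr"

r <- run_qpcr(file.path(data_dir, "qpcr.csv"), "CD25neg", res_dir)

s <- r$folds$summary
for (i in seq_len(nrow(s)))
  message(sprintf("%-9s mean fold %6.2f (SD %.2f, n = %d)",
                  s$group[i], s$mean_fold[i], s$sd_fold[i], s$n[i]))
message(sprintf("one-way ANOVA: F = %.1f, p = %.3g",
                r$comparison$f_stat, r$comparison$p_omnibus))
pw <- r$comparison$pairwise
for (i in seq_len(nrow(pw)))
  message(sprintf("  %s vs %s: diff %7.2f, Tukey p = %.3g %s",
                  pw$group1[i], pw$group2[i], pw$diff[i], pw$p_tukey[i],
                  pw$stars[i]))
message("tables written to ", res_dir)
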