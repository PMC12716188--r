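#!/usr/bin/env Rscript
# Generate the three synthetic datasets at the default study conditions:
#   - single cell: 5000 cells x 2000 genes, 22 clusters, two rare FOXP3+
#     clusters (4.1% and 3.0% of cells), two batches
#   - bulk: 2000 genes x 12 samples (3 CD25 groups x 4 birds, sex
#     covariate), 10% genes with planted |log2 FC| = 2, NB dispersion 0.1
#   - qPCR: CT table with group-level delta-CT shifts of 0 / -3 / -5
# Bulky raw data land in scratch/data (not part of the deliverable);
# ground-truth summaries go to results/.

suppressPackageStartupMessages(library(tregsig))

seed <- 1L
data_dir <- "scratch/data"
res_dir <- "results"
dir.create(file.path(data_dir), recursive = TRUE, showWarnings = FALSE)
dir.create(res_dir, recursive = TRUE, showWarnings = FALSE)

message("single-cell dataset (default preset) ...")
sc <- simulate_sc_dataset(sc_sim_config(seed = seed))
write_mtx_dir(sc$matrix, file.path(data_dir, "sc"))
write_sc_truth(sc$truth, file.path(data_dir, "sc_truth"))
sizes <- table(sc$truth$true_cluster_of_cell)
message(sprintf("  %d cells, %d genes, %d clusters; Treg clusters: %d and %d cells (%.1f%%, %.1f%%)",
                nrow(sc$matrix$counts), ncol(sc$matrix$counts),
                length(sizes), sizes[[1]], sizes[[2]],
                100 * sizes[[1]] / sum(sizes), 100 * sizes[[2]] / sum(sizes)))

message("bulk dataset (3 x 4 CD25 design) ...")
ge <- matrix(0, 2000, 2)
ge[1:100, 2] <- 2    # up in CD25-high
ge[101:200, 2] <- -2 # down in CD25-high
bulk <- simulate_bulk_dataset(bulk_sim_config(
  n_genes = 2000, group_effects = ge,
  sex_effect = rep(c(0.5, 0), c(200, 1800)), seed = seed))
write_bulk_dataset(bulk, file.path(data_dir, "bulk"))
message(sprintf("  %d genes x %d samples; %d genes with planted CD25 effects",
                nrow(bulk$counts), ncol(bulk$counts),
                sum(rowSums(abs(ge)) > 0)))

message("qPCR dataset (FOXP3 vs RPL13, CD25 sort gates) ...")
qp <- simulate_qpcr_dataset(
  c(CD25neg = 8, CD25low = 5, CD25high = 3),  # true delta-CT per gate
  noise_sd = 0.1, n_replicates = 4, seed = seed)
utils::write.csv(qp, file.path(data_dir, "qpcr.csv"), row.names = FALSE,
                 quote = FALSE)
message(sprintf("  %d CT records in %d groups", nrow(qp),
                length(unique(qp$group))))
message("done; raw data under ", data_dir)
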