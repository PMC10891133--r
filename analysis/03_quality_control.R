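#!/usr/bin/env Rscript
# Stage 3: reliability from the pooled QC runs -- per-batch CoV of linear
# protein levels, the >50% average-CoV flag, fragment-level QC
# correlations, and PCA / PLS-DA sample overviews.
suppressMessages(library(diaserum))

metadata <- read.delim("results/metadata.tsv")
qc_mat <- read_matrix_tsv("results/qc_matrix.tsv")
protein <- read_matrix_tsv("results/protein_matrix.tsv")
fragments <- read_fragment_table("results/fragments.tsv",
                                 runs = metadata$run_id)

qc <- compute_cov(qc_mat, metadata, threshold_pct = 50)
write.table(qc$per_protein, "results/qc_cov.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Median QC CoV per batch (%):",
    sprintf("%.1f", qc$per_batch$median_cov), "\n")
cat(sprintf("%d of %d proteins flagged (average CoV > 50%%)\n",
            sum(qc$per_protein$unreliable, na.rm = TRUE),
            nrow(qc$per_protein)))

corr <- qc_correlations(fragments, metadata)
cat(sprintf("Minimum pairwise QC correlation (fragment level): %.3f\n",
            corr$min))

labels <- metadata$cohort[match(colnames(protein), metadata$run_id)]
for (m in c("pca", "plsda")) {
  ord <- ordination(protein, labels, method = m)
  coords <- data.frame(run_id = rownames(ord$coordinates),
                       ord$coordinates, cohort = labels)
  write.table(coords, sprintf("results/ordination_%s.tsv", m),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: components explain %.1f%% + %.1f%% of variance\n",
              toupper(m), ord$explained_pct[1], ord$explained_pct[2]))
}
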