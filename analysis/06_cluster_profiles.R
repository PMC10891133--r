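#!/usr/bin/env Rscript
# Stage 6: median-centered expression signatures clustered by
# complete-linkage on 1 - Pearson correlation, cut into 20 clusters.
suppressMessages(library(diaserum))

protein <- read_matrix_tsv("results/protein_matrix.tsv")
diff <- read.delim("results/differential.tsv")

cl <- cluster_profiles(median_center(protein), k = 20)
write.table(cl$assignment, "results/clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
summ <- summarize_clusters(cl, diff)
write.table(summ, "results/cluster_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d clusters over %d proteins (%d dropped for sparsity)\n",
            cl$k, nrow(cl$assignment), length(cl$dropped)))
cat(sprintf("%d clusters contain primary-tier differential proteins\n",
            sum(summ$contains_significant)))
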