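#!/usr/bin/env Rscript
# Stage 4: overall paired comparison -- two-tailed paired t-test on log10
# protein levels, BH adjustment, 0.05/0.20 significance tiers, directed
# (1 - adjusted p) values, and the volcano table.
suppressMessages(library(diaserum))

metadata <- read.delim("results/metadata.tsv")
protein <- read_matrix_tsv("results/protein_matrix.tsv")
qc <- compute_cov(read_matrix_tsv("results/qc_matrix.tsv"), metadata)

diff <- paired_differential(protein, metadata)
write.table(diff, "results/differential.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(volcano_table(diff, qc), "results/volcano.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

up <- sum(diff$tier %in% "primary" & diff$log10_fc > 0)
dn <- sum(diff$tier %in% "primary" & diff$log10_fc < 0)
cat(sprintf("%d proteins elevated and %d lowered in convalescents\n",
            up, dn), "  (primary tier, adjusted p < 0.05)\n")
truth <- read.delim("results/truth_effects.tsv")
detected <- diff$protein[diff$tier %in% "primary"]
cat(sprintf("Recovery: %d of %d injected effects detected\n",
            sum(truth$protein[truth$effect_log10 != 0] %in% detected),
            sum(truth$effect_log10 != 0)))
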