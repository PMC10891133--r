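#!/usr/bin/env Rscript
# Stage 7: hexose-modification occupancy -- modification level
# log2(mod/(mod+unmod)) per peptide and run, 20% missingness filter,
# paired test of convalescents vs controls with BH adjustment.
suppressMessages(library(diaserum))

metadata <- read.delim("results/metadata.tsv")
ptm <- read.delim("results/ptm_intensities.tsv")

lv <- filter_ptm_peptides(ptm_level_matrix(ptm), max_missing_frac = 0.20)
res <- test_occupancy(lv, metadata)
write.table(res, "results/ptm_occupancy.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("%d modified peptides pass the missingness filter\n",
            nrow(lv)))
cat(sprintf("%d peptides with significantly shifted occupancy (adj p < 0.05)\n",
            sum(res$p_adj < 0.05, na.rm = TRUE)))
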