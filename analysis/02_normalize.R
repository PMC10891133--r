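#!/usr/bin/env Rscript
# Stage 2: fragment missingness filter, per-batch Gaussian-kernel drift
# correction on run order (sd 5 runs), cross-batch median equalization,
# correlation-ranked fragment selection, and log10 protein rollup.
suppressMessages(library(diaserum))

metadata <- read.delim("results/metadata.tsv")
fragments <- read_fragment_table("results/fragments.tsv",
                                 runs = metadata$run_id)
pm <- normalize_cohort(fragments, metadata, kernel_sd = 5)

write_matrix_tsv(pm$protein, "results/protein_matrix.tsv")
write_matrix_tsv(pm$qc, "results/qc_matrix.tsv")
write.table(pm$provenance, "results/provenance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Removed %d fragments with >50%% missingness\n",
            pm$n_fragments_removed))
cat(sprintf("Protein matrix: %d proteins x %d subject runs (+%d QC)\n",
            nrow(pm$protein), ncol(pm$protein), ncol(pm$qc)))
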