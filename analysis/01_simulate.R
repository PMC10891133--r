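#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohort that emulates the study design --
# 29 matched convalescent/control pairs in 4 batches with interleaved
# pooled QC runs, run-order drift, and hexose-modified peptide channels.
suppressMessages(library(diaserum))
dir.create("results", showWarnings = FALSE)

design <- cohort_design()  # study-design defaults; seed 1
co <- simulate_cohort(design)

write.table(co$metadata, "results/metadata.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_fragment_table(co$fragments, "results/fragments.tsv")
write.table(co$ptm$table, "results/ptm_intensities.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(protein = names(co$fragments$truth$effects),
                       effect_log10 = co$fragments$truth$effects),
            "results/truth_effects.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Simulated %d runs (%d subject, %d QC) in %d batches\n",
            nrow(co$metadata), sum(co$metadata$cohort != "qc"),
            sum(co$metadata$cohort == "qc"), design$n_batches))
cat(sprintf("%d fragments over %d proteins; %d with true effects\n",
            nrow(co$fragments$intensity), design$n_proteins,
            sum(co$fragments$truth$effects != 0)))
cat(sprintf("days-titer R^2 = %.2f (design target %.2f)\n",
            titer_days_r2(co$metadata), design$r2_days_titer))
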