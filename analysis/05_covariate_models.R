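#!/usr/bin/env Rscript
# Stage 5: the six linear-regression families -- univariate and
# multivariate models of Age, Sex, Race, Symptoms, and Days since
# diagnosis on control levels, convalescent levels, and paired log10
# ratios (the latter with an Age x Sex interaction). Titer never enters.
suppressMessages(library(diaserum))

metadata <- read.delim("results/metadata.tsv")
protein <- read_matrix_tsv("results/protein_matrix.tsv")

datasets <- build_datasets(protein, metadata)
fits <- fit_models(datasets)
write.table(fits, "results/model_fits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

diff <- read.delim("results/differential.tsv")
grid <- significance_grid(fits, diff)
write.table(data.frame(protein = rownames(grid$directed), grid$directed,
                       check.names = FALSE),
            "results/significance_grid.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Fitted %d protein x model x term rows\n", nrow(fits)))
for (v in c("Age", "Sex", "Race", "Symptoms", "DaysSinceDiagnosis")) {
  sub <- fits[fits$form == "multivariate" & fits$variable == v, ]
  cat(sprintf("  %-18s %3d primary-tier associations\n", v,
              sum(sub$p_adj < 0.05, na.rm = TRUE)))
}
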