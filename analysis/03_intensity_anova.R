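#!/usr/bin/env Rscript

# Intensity side of the workflow: per-treatment means/SE/N of log10
# precursor intensity for the strongest selected symbol, one-way ANOVA
# across treatments, additive two-way ANOVA (treatment + peptide) and
# quantile/box-plot exports. Tables land in results/intensity/.

suppressPackageStartupMessages(library(pepfreq))
library(data.table)

stopifnot(file.exists("results/comparison/frequency_TRYP.tsv"))
out <- "results/intensity"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

freq <- read_frequency_table("results/comparison/frequency_TRYP.tsv")
sym <- freq[order(-chi2)]$gene_symbol[1]
cat("analyzing the top-ranked symbol:", sym, "\n")

case <- filter_min_intensity(read_psm_table("results/sim/case_psms.tsv"))
ctrl <- filter_min_intensity(read_psm_table("results/sim/control_psms.tsv"))
rec <- to_intensity_records(rbind(case, ctrl))
sub <- rec[gene_symbol == sym]

tm <- treatment_means(rec, symbol = sym)
fwrite(tm, file.path(out, sprintf("means_%s.tsv", sym)), sep = "\t",
       quote = FALSE)
cat("per-treatment means (log10 intensity):\n")
print(tm)

a1 <- anova_oneway(sub$log10_intensity, sub$treatment_id)
cat("\none-way ANOVA across treatments:\n")
print(a1)
fwrite(as.data.table(a1$table), file.path(out, "anova_oneway.tsv"),
       sep = "\t", quote = FALSE)

if (length(unique(sub$peptide)) >= 2) {
  a2 <- anova_twoway(sub$log10_intensity, sub$treatment_id, sub$peptide,
                     names = c("treatment", "peptide"))
  cat("\ntwo-way additive ANOVA (treatment + peptide, Type II SS):\n")
  print(a2)
  fwrite(as.data.table(a2$table), file.path(out, "anova_twoway.tsv"),
         sep = "\t", quote = FALSE)
}

ex <- export_distribution(sub$log10_intensity, sub$treatment_id)
fwrite(ex$summary, file.path(out, "boxplot_summary.tsv"), sep = "\t",
       quote = FALSE)
cat("\nwrote", out, "\n")
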