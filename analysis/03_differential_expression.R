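#!/usr/bin/env Rscript
# Stage 3: expression filtering and NB Wald contrasts.
#
# Genes below mean FPKM 1 are removed; the remaining genes are tested in
# the five pairwise contrasts (parents; each hybrid vs each parent) plus
# the two mid-parent contrasts that feed the additivity call, with BH
# adjustment within each contrast.

library(hetexpress)

cm <- read_count_matrix("results/sim/counts.tsv", "results/sim/lengths.tsv")
samples <- read_sample_sheet("results/sim/samples.tsv")

de <- run_contrasts(cm, samples)
cat("Genes in:", nrow(cm$counts), "| filtered:", de$n_filtered,
    "| tested:", length(de$retained_genes), "\n\nDEGs (padj < 0.05):\n")
for (nm in names(de$results)) {
  r <- de$results[[nm]]
  write.table(r, file.path("results", paste0("de_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("  %-12s %4d\n", nm, sum(r$p_adjusted < 0.05)))
}
cat("\nThe parent contrast dominates, as expected when every planted",
    "non-conserved gene separates the purebred lines.\n")
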