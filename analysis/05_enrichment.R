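#!/usr/bin/env Rscript
# Stage 5: over-representation of over-dominant genes.
#
# The universe is the filtered (tested) gene population; the study lists
# are each cross's over-dominant genes. The bundled synthetic GMT plants
# two metabolic pathways on the over-dominant block, so both should rise
# to the top with FDR < 0.05 while the background pathways stay flat.

library(hetexpress)

sets <- read_gmt(system.file("extdata", "synthetic_pathways.gmt",
                             package = "hetexpress", mustWork = TRUE))
universe <- read.delim("results/de_P2_vs_P1.tsv")$gene_id

for (cr in c("F1A", "F1B")) {
  calls <- read.delim(file.path("results", paste0("modes_", cr, ".tsv")))
  study <- calls$gene_id[calls$category == "over"]
  cat("\n", cr, ": ", length(study), " over-dominant genes tested against ",
      length(sets), " sets (universe ", length(universe), ")\n", sep = "")
  enr <- hypergeom_ora(study, universe, sets)
  write.table(enr, file.path("results", paste0("ora_over_", cr, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  print(enr[, c("set_name", "k", "K", "p_value", "fdr")], digits = 3)
  cat("significant at FDR < 0.05:",
      paste(significant_sets(enr), collapse = ", "), "\n")
}
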