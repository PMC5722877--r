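#!/usr/bin/env Rscript
# Stage 2 — gene set enrichment per species.
#
# Reads the per-species DE tables, calls DE genes (|log2FC| >= 1, BH < 0.05,
# direction ignored), restricts to the GO terms annotated in every species,
# runs one-sided Fisher tests per (species, term) and applies a
# Benjamini-Yekutieli correction across the universe within each species.

library(drydisp)

out <- "results/study"
gene_dir <- file.path(out, "data", "genes")
tabs <- lapply(list.files(gene_dir, full.names = TRUE), read_gene_table)
names(tabs) <- sub("\\.tsv$", "", list.files(gene_dir))

prof <- enrich_all(tabs)
cat(sprintf("shared GO universe: %d terms (%s)\n", length(prof$universe),
            paste(names(table(prof$namespaces)),
                  table(prof$namespaces), collapse = " + ")))
cat(sprintf("significant (species, term) cells: %.1f%%\n",
            100 * mean(prof$significant)))

for (what in c("odds_ratio", "p_fisher", "p_by", "significant")) {
  f <- file.path(out, paste0("enrichment_", what, ".csv"))
  utils::write.csv(data.frame(species = rownames(prof[[what]]),
                              prof[[what]] + 0, check.names = FALSE),
                   f, row.names = FALSE)
}
cat("wrote enrichment matrices under", out, "\n")
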