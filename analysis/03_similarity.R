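#!/usr/bin/env Rscript
# Stage 3 — species dissimilarity matrices from every similarity source.
#
# Expression: hierarchical clustering of the binary significance profiles
# (the headline source; odds-ratio clustering retained as an alternative),
# cophenetic path lengths as delta. Traits: Euclidean distance on the first
# two PC axes. Phylogeny: patristic distance. Wilting and each tolerance:
# absolute scalar differences.

library(drydisp)

out <- "results/study"
gene_dir <- file.path(out, "data", "genes")
tabs <- lapply(list.files(gene_dir, full.names = TRUE), read_gene_table)
names(tabs) <- sub("\\.tsv$", "", list.files(gene_dir))
prof <- enrich_all(tabs)
pn <- split_profile(prof)

traits <- utils::read.csv(file.path(out, "data", "traits.csv"), row.names = 1)
wilt <- utils::read.csv(file.path(out, "data", "wilting.csv"))
tol <- utils::read.csv(file.path(out, "data", "tolerances.csv"),
                       row.names = 1)
tree <- read_newick(file.path(out, "data", "phylogeny.nwk"))
cross_validate_labels(genes = names(tabs), tree = tree$tip.label,
                      traits = rownames(traits))

dists <- list(
  `expression-BP` = expression_distances(pn$BP, source = "expression-BP")$distances,
  `expression-MF` = expression_distances(pn$MF, source = "expression-MF")$distances,
  `expression-BP-oddsratio` =
    expression_distances(pn$BP, use = "odds_ratio",
                         source = "expression-BP-or")$distances,
  traits = trait_pc_distances(as.matrix(traits)),
  phylogeny = patristic_distances(tree),
  wilting = scalar_distances(stats::setNames(wilt$wilting_days, wilt$species),
                             source = "wilting"))
for (tl in colnames(tol)) {
  dists[[paste0("tolerance-", tl)]] <-
    scalar_distances(stats::setNames(tol[[tl]], rownames(tol)),
                     source = paste0("tolerance-", tl))
}

for (nm in names(dists)) {
  write_dist_csv(dists[[nm]], file.path(out, paste0("dist_", nm, ".csv")))
  cat(sprintf("%-26s mean delta = %.3f\n", nm,
              mean(dists[[nm]][upper.tri(dists[[nm]])])))
}
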