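#!/usr/bin/env Rscript
# Stage 4 — differential expression of genes and immune populations.
#
# Kruskal-Wallis omnibus across the four groups with BH-FDR at 5%,
# Wilcoxon post-hoc contrasts of each mutated group vs wild type, signed
# fold changes, and the Venn partition of the three contrasts' significant
# genes (up and down separately). The identical machinery is applied to
# the immune-score rows. Writes de_genes.tsv, de_cell_scores.tsv and
# venn.tsv under results/.

library(immunopanel)

norm <- as.matrix(read.delim("results/normalized.tsv", row.names = 1,
                             check.names = FALSE))
scores <- as.matrix(read.delim("results/cell_scores.tsv", row.names = 1,
                               check.names = FALSE))
samples <- read_samples("results/cohort/samples.tsv")

ref <- "EGFR/ERBB2wt"
others <- setdiff(unique(samples$group), ref)
pairs <- lapply(others, function(g) c(g, ref))

de <- de_table(norm, samples, pairs = pairs, fdr = 0.05)
write_tsv(de, "results/de_genes.tsv")
cat(sum(de$kw_sig), "of", nrow(de),
    "genes omnibus-significant at FDR 5%\n")
planted <- de[de$feature == "GENE0030", ]
cat(sprintf("planted gene GENE0030: FC = %.2f, adj p = %.2g (truth -2.5)\n",
            planted[[paste0("fc_EGFR-Ex20mut.vs.", ref)]],
            planted[[paste0("p_adj_EGFR-Ex20mut.vs.", ref)]]))

de_cells <- de_table(scores, samples, pairs = pairs, fdr = 0.05)
write_tsv(de_cells, "results/de_cell_scores.tsv")
cat(sum(de_cells$kw_sig), "score rows omnibus-significant\n")

venn_rows <- list()
for (direction in c("up", "down")) {
  sets <- lapply(others, function(g) significant_set(de, c(g, ref), direction))
  vp <- venn_partition(sets[[1]], sets[[2]], sets[[3]], names = others)
  venn_rows[[direction]] <- data.frame(
    direction = direction, cell = names(vp), n = lengths(vp),
    genes = vapply(vp, paste, character(1), collapse = ","), row.names = NULL)
}
venn <- do.call(rbind, venn_rows)
write_tsv(venn, "results/venn.tsv")
print(venn[, c("direction", "cell", "n")])
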