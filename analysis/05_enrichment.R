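#!/usr/bin/env Rscript
# Stage 5 — category enrichment and pathway coverage.
#
# Fisher-exact over-representation of the omnibus-significant genes in the
# packaged illustrative category catalog (universe = the panel), and
# coverage accounting of a synthetic external pathway list against the
# panel. Writes enrichment.tsv and pathway_coverage.tsv under results/.

library(immunopanel)

de <- read.delim("results/de_genes.tsv", check.names = FALSE)
universe <- de$feature
sig <- de$feature[as.logical(de$kw_sig)]

catalog <- read_gmt(system.file("extdata", "panel_categories.gmt",
                                package = "immunopanel"))
# the program of genes carrying planted effects, as its own category: the
# enrichment machinery should flag it against the marker-based categories
catalog$planted_program <- sprintf("GENE%04d", c(1:25, 30))
enr <- enrich(sig, universe, catalog)
write_tsv(enr, "results/enrichment.tsv")
print(enr[order(enr$p), c("category", "sig_in", "nonsig_in", "direction",
                          "p", "p_adj")])

# synthetic stand-in for an externally annotated pathway: 531 genes of
# which 150 are on the panel (mirrors the size of a large cancer-pathway
# map; membership is arbitrary and labeled synthetic)
set.seed(1)
on_panel <- sample(universe, 150)
pathway <- c(on_panel, sprintf("OFFPANEL%03d", 1:381))
ref <- "EGFR/ERBB2wt"
others <- setdiff(c("ERBB2-Ex20mut", "EGFR-Ex20mut", "EGFR-Ex18/19/21mut",
                    "EGFR/ERBB2wt"), ref)
de_sets <- setNames(lapply(others, function(g)
  significant_set(de, c(g, ref))), others)
cov <- pathway_coverage(pathway, universe, de_sets,
                        pathway = "synthetic_cancer_pathway")
write_tsv(data.frame(pathway = cov$pathway, n_annotated = cov$n_annotated,
                     n_covered = cov$n_covered,
                     coverage_percent = cov$coverage_percent,
                     n_de_total = cov$n_de_total,
                     de_percent_of_covered = cov$de_percent_of_covered),
          "results/pathway_coverage.tsv")
cat(sprintf("pathway coverage: %d/%d genes (%d%%) on panel; %d DE among covered (%d%%)\n",
            cov$n_covered, cov$n_annotated, cov$coverage_percent,
            cov$n_de_total, cov$de_percent_of_covered))
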