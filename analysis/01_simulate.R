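#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study cohort.
#
# 98 samples in four driver-defined groups (19 ERBB2-Ex20mut, 13
# EGFR-Ex20mut, 40 EGFR-Ex18/19/21mut, 26 EGFR/ERBB2wt), a 770-gene
# immune panel with control probes, latent hot/cold infiltration, and a
# designed set of planted effects vs the wild-type group so the downstream
# stages have known structure to find:
#   GENE0001-0010  up   in all three mutated groups   (shared Venn core)
#   GENE0011-0016  down in all three mutated groups
#   GENE0017-0021  up   only in ERBB2-Ex20mut
#   GENE0022-0025  up   in both exon-20 groups        (pairwise Venn cell)
#   GENE0030       FC -2.5 in EGFR-Ex20mut            (headline effect)
# Writes counts, probe and sample annotations, and the ground-truth
# tables under results/cohort/.

library(immunopanel)

seed <- 20211L
out <- "results/cohort"

mut <- c("ERBB2-Ex20mut", "EGFR-Ex20mut", "EGFR-Ex18/19/21mut")
plant <- function(genes, groups, lfc)
  expand.grid(gene_id = genes, group_a = groups, stringsAsFactors = FALSE) |>
    transform(group_b = "EGFR/ERBB2wt", log2fc = lfc)
eff <- rbind(
  plant(sprintf("GENE%04d", 1:10), mut, 1.2),
  plant(sprintf("GENE%04d", 11:16), mut, -1.2),
  plant(sprintf("GENE%04d", 17:21), "ERBB2-Ex20mut", 1.4),
  plant(sprintf("GENE%04d", 22:25), c("ERBB2-Ex20mut", "EGFR-Ex20mut"), 1.4),
  plant("GENE0030", "EGFR-Ex20mut", -log2(2.5)))
cfg <- simulation_config(planted_effects = eff, seed = seed)
sim <- simulate_cohort(cfg)
write_cohort(sim, out, rcc = FALSE)

cat("cohort:", ncol(sim$counts), "samples x", nrow(sim$counts), "probes\n")
print(table(sim$samples$group))
cat("planted hot/cold truth:", sum(sim$truth$samples$state == "hot"), "hot /",
    sum(sim$truth$samples$state == "cold"), "cold\n")
cat("written to", out, "\n")
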