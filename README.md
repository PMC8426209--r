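# immunopanel

Immune microenvironment profiling from targeted gene-expression panels.

## The problem

Targeted panels of a few hundred immune-related transcripts (the
NanoString nCounter family is the archetype) let pathology labs read the
tumor microenvironment out of routine FFPE biopsies. A common study
design profiles a cohort split into driver-mutation subgroups — e.g. lung
adenocarcinomas with ERBB2 exon-20 insertions, EGFR exon-20 insertions,
classical EGFR mutations (exons 18/19/21), or neither — and asks whether
immune infiltration and specific immune programs differ by genotype.

`immunopanel` implements that analysis end to end, plus a synthetic
cohort generator with known ground truth so every stage is testable
without access to any particular study's (often undeposited) raw data:

1. **Normalization** — positive-control scaling, negative-control
   background flooring (mean + 2 SD), housekeeping geometric-mean
   scaling, log2(x + 1); every step switchable.
2. **Immune-cell scores** — for 14 populations, the score is the
   arithmetic mean of the population's marker genes on the log2 scale
   (Danaher-style marker means), plus total TILs (mean of population
   scores) and cytolytic activity (mean of log2 GZMA and PRF1).
3. **Hot/cold classification** — hierarchical clustering of samples by
   the score matrix (Euclidean distance on centered rows, average
   linkage), cut at k = 2; the higher-TIL cluster is *hot*. Cluster vs
   genotype association uses the two-sided Fisher exact test.
4. **Differential expression** — Kruskal–Wallis omnibus across groups,
   Wilcoxon post-hoc contrasts, Benjamini–Hochberg FDR at 5%, signed
   fold changes `FC = 2^(Δ log2 means)` reported as `−1/FC` when below 1,
   and the 7-cell Venn partition of three contrasts vs the wild-type
   group.
5. **Enrichment & coverage** — Fisher-exact over-representation of
   significant genes in GMT categories with the panel as universe, and
   coverage accounting of external pathway gene lists.

## Worked example

```r
library(immunopanel)

# a 98-sample cohort: groups of 19/13/40/26, 770-gene panel, hot/cold
# infiltration, one planted -2.5 fold change on GENE0001
eff <- data.frame(gene_id = "GENE0001", group_a = "EGFR-Ex20mut",
                  group_b = "EGFR/ERBB2wt", log2fc = -log2(2.5))
sim  <- simulate_cohort(simulation_config(planted_effects = eff, seed = 20211))
norm <- normalize_counts(sim$counts, sim$probes)
scores <- score_matrix(norm)

cl  <- hcluster(scores[1:14, ], axis = "columns", k = 2)
lab <- label_hot_cold(cl, scores["total_TILs", ])
table(lab)
#> lab
#> cold  hot
#>   67   31

# association of hot/cold with genotype, via the printed worked example
# table (cold/hot x EGFR-Ex20mut/wild type = [[10,3],[9,17]])
association_test(matrix(c(10, 3, 9, 17), 2, byrow = TRUE))$p.value
#> [1] 0.01870113

de <- de_table(norm, sim$samples,
               pairs = list(c("EGFR-Ex20mut", "EGFR/ERBB2wt")),
               gate_on_omnibus = FALSE)
de[de$feature == "GENE0001",
   c("fc_EGFR-Ex20mut.vs.EGFR/ERBB2wt", "p_EGFR-Ex20mut.vs.EGFR/ERBB2wt")]
#>    fc_EGFR-Ex20mut.vs.EGFR/ERBB2wt p_EGFR-Ex20mut.vs.EGFR/ERBB2wt
#> 61                       -1.913892                   0.0002338437
```

The Fisher p of 0.0187 matches the printed 0.018 of the motivating
cohort. This particular cohort estimates the planted −2.5 fold change as
−1.91 (raw Wilcoxon p 0.00023; after BH correction across the 770-gene
pairwise family, 0.18) — a reminder that a single n = 13 vs n = 26
contrast is noisy. Across 100 replicate cohorts the median estimate is
−2.47 and the effect is detected at FDR 5% in 97% of replicates, as
`scripts/acceptance.R` recomputes.

## The analysis workflow

The `analysis/` directory runs the full study as numbered drivers, each a
thin narrative over the package functions, writing tables under
`results/`:

| script | stage | outputs |
|---|---|---|
| `01_simulate.R` | synthetic cohort with ground truth | `results/cohort/*.tsv` |
| `02_normalize_score.R` | normalization + immune scores | `normalized.tsv`, `cell_scores.tsv` |
| `03_hot_cold.R` | hot/cold clustering + association | `clusters.tsv`, `cluster_association.tsv` |
| `04_diffexp.R` | omnibus/post-hoc DE + Venn | `de_genes.tsv`, `de_cell_scores.tsv`, `venn.tsv` |
| `05_enrichment.R` | category enrichment + coverage | `enrichment.tsv`, `pathway_coverage.tsv` |
| `06_run_all.R` | one-shot orchestrated run (`run_all()`) | `full_run/` + `run_summary.json` |

All output tables are TSV with fixed column order: matrices carry their
id column first (`gene_id` / `population` / `sample_id`), DE tables are
`feature`, per-group means, omnibus columns, then per-contrast
p / adjusted p / fold change / flag blocks; each `run_all()` invocation
also writes a JSON run summary (version, seed, group sizes, hot/cold
counts, significant-gene counts, warnings).

## Vignette

`vignettes/immune-panel-workflow.Rmd` documents the model: the
normalization steps and their order, the marker-mean score construction
and the packaged 14-population catalog, the two-state infiltration model
behind the generator and what it does and does not emulate, the testing
design (omnibus gate, FDR families, fold-change convention), and the
package's handling of ties and degenerate inputs.
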