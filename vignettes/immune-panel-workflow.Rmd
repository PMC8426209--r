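---
title: "Profiling the tumor immune microenvironment from targeted expression panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the tumor immune microenvironment from targeted expression panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunopanel)
```

## The problem

Targeted expression panels of a few hundred immune-related genes (the
NanoString nCounter family of assays is the canonical example) are a
practical way to read out the tumor microenvironment (TME) from routine
FFPE biopsies. A typical study design profiles a cohort of tumors split
into genetically defined subgroups — here, lung adenocarcinomas carrying
ERBB2 exon-20 insertions, EGFR exon-20 insertions, classical EGFR
mutations (exons 18/19/21), or neither — and asks three questions:

1. How infiltrated is each tumor overall (immunologically *hot* vs *cold*),
   and does the hot/cold split associate with the driver genotype?
2. Which specific immune cell populations differ between genotype groups?
3. Which individual genes and functional categories differ?

`immunopanel` implements this workflow end to end, together with a
synthetic cohort generator with known ground truth, so that every stage —
normalization, scoring, clustering, testing — can be validated without
access to any particular study's raw data.

## Normalization

Raw panel counts are converted to log2 expression in four switchable steps
(`normalization_params()`), applied per sample in this order:

1. **Positive-control scaling.** Each sample is multiplied by
   (grand geometric mean of positive-control counts) / (its own
   positive-control geometric mean). This removes lane-level efficiency
   differences.
2. **Background flooring.** Endogenous and housekeeping counts are floored
   at mean + 2 SD of the sample's negative controls. Flooring (rather than
   subtraction) preserves nonnegativity; mean + 2 SD is the common
   nCounter convention.
3. **Housekeeping scaling.** Each sample is multiplied by (grand geometric
   mean of housekeeping geometric means) / (its own housekeeping geometric
   mean). After this step the housekeeping geometric mean is equal across
   samples by construction, which removes RNA-input differences.
4. **log2(x + 1).** The pseudocount (default 1) bounds the transform at
   zero counts; it is configurable for users who prefer excluding zeros.

Control probes are dropped from the output, which contains exactly the
endogenous genes in panel order.

## Immune cell scores

The relative abundance of an immune population is the **arithmetic mean of
its marker genes' log2 normalized expression** — the marker-mean (Danaher
style) construction, equivalent to a geometric mean on the linear scale.
The packaged catalog (`read_marker_catalog()`,
`inst/extdata/immune_markers.yaml`) covers 14 populations: B cells, CD45+
cells, CD56dim NK cells, CD8+ T cells, cytotoxic cells, dendritic cells,
exhausted CD8+ T cells, macrophages, mast cells, neutrophils, NK cells,
T cells, Th1 cells and Treg. The catalog is data, not code: it is an
editable YAML and can be overridden per run. Two entries deserve comment:

* *Cytotoxic cells* use the ten granzyme/perforin-axis markers PRF1, GZMA,
  GZMB, GZMH, GNLY, CTSW, KLRB1, KLRD1, KLRK1, NKG7; *CD8+ T cells* use
  CD8A and CD8B only — the broader population captures all
  granzyme-releasing cells, the narrower one the CD8 lineage.
* The CD56dim NK killer-cell immunoglobulin-like receptor marker is
  encoded as the two full symbols KIR3DL1 and KIR3DL2.

Two composites complete the score matrix: **total TILs**, the mean of a
configurable subset of population scores (default: all 14 — the exact
subset entering the published total-TIL composite is not restated in the
literature we follow, so the permissive default is used and documented),
and **cytolytic activity**, the mean of log2 GZMA and PRF1, identical by
definition to `cell_score(norm, c("GZMA", "PRF1"))`.

Because scores are means on the log2 scale, they are translation
equivariant (adding c to every marker shifts the score by c) and monotone
in each marker — both properties are tested.

## Hot/cold classification

Samples are clustered by their 14-population score matrix
(`hcluster()`): rows are mean-centered, distances are Euclidean, linkage
is average, and the tree is cut at exactly k = 2. Distance and linkage are
deliberately configurable — published heatmaps rarely state them, and the
exact dendrogram of any one study is generally not reproducible; the
defaults are the common expression-heatmap convention. The cluster with
the higher mean total-TIL score is labeled **hot**, the other **cold**
(`label_hot_cold()`); an exact tie labels the larger cluster cold, an
arbitrary but documented convention. Cutting at k = 2 (rather than at a
height threshold) matches the dichotomous hot/cold reading of such
cohorts.

Cluster–genotype association uses the two-sided Fisher exact test
(`association_test()`), with r x c tables handled exactly up to a total-N
guard (default 200) and by seeded Monte-Carlo simulation (100,000 tables)
beyond it, flagged in the output.

## Differential expression

Per feature (gene, or immune-score row — the same machinery serves both):

* **Omnibus:** Kruskal–Wallis across the four groups (tie-corrected H,
  chi-squared reference with 3 df).
* **Post hoc:** two-sided Wilcoxon rank-sum per group pair; exact when the
  combined n is at most 25 with no ties, normal approximation with
  continuity correction otherwise (the switch is recorded per test).
* **Multiplicity:** Benjamini–Hochberg, applied across genes within the
  omnibus family and separately across genes within each pairwise family.
  The family structure is a design choice (studies rarely state theirs);
  it is documented here and configurable through which pairs are run.
  Pairwise significance flags are additionally gated on omnibus
  significance by default (`gate_on_omnibus`), mirroring an omnibus-gated
  post-hoc design; the gate can be switched off, e.g. for single-contrast
  power studies where the pairwise family is the object of interest.
* **Fold changes** are computed from the difference of group means of log2
  values: r = 2^(meanA − meanB), reported as r when r ≥ 1 and as −1/r
  otherwise, so a negative value means lower expression in the first
  group. This matches the signed linear-scale convention of the field.

`venn_partition()` decomposes the three mutated-vs-wild-type significant
sets (up- and down-regulated separately) into the seven disjoint Venn
cells.

## Enrichment and pathway coverage

`enrich()` runs one two-sided Fisher exact test per annotation category on
the (in set / out) x (significant / not) table. The universe is the
**panel**, not the genome: a targeted assay's denominators are
panel-relative, and using the genome would manufacture spurious
enrichment. Depletion is reported through the same two-sided p with the
direction read off the odds ratio. The category catalog is user-supplied
GMT data; a small illustrative catalog built from the marker signatures
(including a cytotoxicity category) ships with the package for tests and
examples. `pathway_coverage()` reports how much of an externally annotated
pathway (e.g. a KEGG gene list supplied as GMT) the panel covers and how
many covered genes are differentially expressed per comparison, with
percentages rounded to whole numbers in the field's reporting style.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the package is built
around. Defaults, chosen once as the study conditions:

* **Design:** 98 samples in groups of 19 / 13 / 40 / 26
  (ERBB2-Ex20mut, EGFR-Ex20mut, EGFR-Ex18/19/21mut, EGFR/ERBB2wt); a
  770-gene endogenous panel (marker genes keep their real symbols, the
  rest are synthetic ids), 20 housekeeping, 8 negative and 6 positive
  control probes.
* **Infiltration:** each sample is hot with its group's hot fraction
  (defaults 6/19, 3/13, 16/40, 17/26 — the observed hot/cold split of the
  motivating cohort); each population's latent log2 abundance is
  Normal(state mean, 1) with hot and cold means 2 latent SD apart. The
  two-state mixture (rather than a continuum) matches the dichotomous
  hot/cold reading and gives the recovery tests discrete truth.
* **Expression:** a marker gene's log2 mean is its baseline plus its
  population's latent abundance with slope fixed at 1, so the score scale
  equals the latent scale and recovery is directly interpretable.
  Baselines are Uniform(5, 10) log2 — the broad mid-range of a panel
  assay. Non-marker genes take baseline plus any planted group-contrast
  effect.
* **Counts:** negative binomial with dispersion 0.1 — integer counts with
  the overdispersion typical of FFPE panel data; at median panel counts
  this yields a within-group SD of about 0.5 log2, the regime the power
  analyses assume. Library factors are 2^Normal(0, 0.2); positive
  controls follow a fixed geometric ladder times the library factor,
  negative controls are Poisson with mean 2 and independent of library
  size.
* **Housekeeping genes** are unaffected by state and effects — their
  stability is an assumption of housekeeping normalization, and the
  generator enforces it so the tests can verify the normalization path in
  the regime it is designed for.

`simulate_null()` keeps the identical model but removes planted effects
and equalizes hot fractions across groups, so group labels carry no
signal; it is the calibration harness for test size and FDR control.

All randomness flows from one master seed (`withr::with_seed`), with a
fixed documented draw order (baselines, states, latents, library factors,
counts); the same configuration reproduces byte-identical outputs.

**What the generator does not emulate:** the real panel's per-gene
abundance distribution and correlation structure, sample-quality
artifacts (FFPE degradation gradients, lane effects beyond a scalar
library factor), within-state heterogeneity of infiltration beyond one
shared latent SD, and any relation between driver genotype and individual
gene expression other than the effects explicitly planted. Passing
recovery tests therefore demonstrates correctness of the computational
pipeline under the stated generative assumptions, not biological validity
on real cohorts.

## Validation and problem sizes

The test suite validates the statistical core against independent
oracles: a brute-force hypergeometric enumeration for the two-sided
Fisher p (shared by `association_test()` and `enrich()`), and the raw
step-up definition for `bh_adjust()`. Calibration and recovery studies
run at these sizes, chosen as the package's simulation budget:

* omnibus size: 130 null cohorts x 770 genes (100,100 gene-replicates),
  rejection at alpha = 0.05 expected in [0.045, 0.055];
* FDR control: 200 cohorts of 300 genes with 10% planted non-null
  (log2 effects of +/-1.322), mean false-discovery proportion of
  BH selection at 5% expected at or below 0.075;
* power: a planted signed fold change of -2.5 between the n = 13 and
  n = 26 groups, 50-100 replicates, detection at FDR 5% expected in at
  least 80% with the median estimate within 15%;
* recovery: Spearman rho of at least 0.9 between each population's latent
  abundance and its score across 98 samples, and at least 95% agreement
  of hot/cold labels with the planted states.

`scripts/acceptance.R` recomputes all of these from scratch from a single
seed and writes them as JSON.

## Numerical choices and degenerate inputs

* Complete ties (a feature constant across all samples) define H = 0,
  p = 1 for the omnibus and p = 1 for the rank-sum test, rather than the
  NaN of the raw tie-corrected formulas.
* Degenerate contingency margins (an all-zero row or column) return p = 1
  with a warning — there is no evidence against independence in an empty
  margin.
* Geometric means require strictly positive input; where control counts
  can be zero, a half-count offset is applied before the geometric mean,
  and all-zero housekeeping in a sample is a hard error naming the
  sample.
* Cluster labels are numbered by first appearance in input order, making
  `hcluster()` deterministic and permutation-stable up to relabeling.
* All TSV output uses a fixed 15-significant-digit rendering so that
  equal numbers are equal bytes; pipeline determinism is asserted at the
  byte level.

## Known limitations

* The normalization default is the standard nCounter workflow, but
  published studies frequently defer their exact pipeline to earlier
  work; when matching a specific study, check each switch in
  `normalization_params()` against that study's references.
* Cluster-association p-values depend on the clustering that produced the
  hot/cold labels; with other distances or linkages the 2 x c tables, and
  hence the p-values, change. The package treats the dendrogram as a
  modeling choice, not a reproducible statistic.
* Enrichment results are only as good as the supplied GMT catalogs; the
  packaged category file is illustrative, not a reconstruction of any
  commercial annotation.
* No parametric (limma-style) alternative and no covariate adjustment are
  provided; the target design is rank-based and unadjusted.
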