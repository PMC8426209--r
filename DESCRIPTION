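Package: immunopanel
Title: Immune Microenvironment Profiling from Targeted Expression Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for targeted immune gene-expression panels
    (NanoString nCounter style) applied to driver-defined tumor subgroups:
    control-based and housekeeping normalization of panel counts, marker-gene
    immune-cell scoring (14 Danaher-style populations, total TILs, cytolytic
    activity), hot/cold tumor classification by hierarchical clustering,
    Kruskal-Wallis omnibus and Wilcoxon post-hoc differential expression with
    Benjamini-Hochberg FDR control, Fisher-exact over-representation and
    pathway-coverage accounting, plus a negative-binomial cohort simulator
    with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
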