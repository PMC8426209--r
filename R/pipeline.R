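#' Pipeline run configuration
#'
#' A single object describing an end-to-end run: the cohort source (either
#' a [simulation_config()] or paths to counts/probes/samples tables, or RCC
#' files), normalization and clustering parameters, the reference group for
#' the contrast design, the FDR level, optional gene-set catalogs, and the
#' output directory. All randomness flows from the configured seed.
#'
#' @param out_dir output directory for stage tables and the run summary.
#' @param sim a [simulation_config()]; if `NULL`, `counts_path`,
#'   `probes_path` and `samples_path` (or `rcc_paths` + `samples_path`)
#'   must be given.
#' @param counts_path,probes_path,samples_path input tables (see
#'   [read_counts()], [read_samples()]).
#' @param rcc_paths character vector of RCC files (alternative entry point).
#' @param gmt_path optional GMT catalog for category enrichment.
#' @param pathway_gmt_path optional GMT of external pathway gene lists for
#'   coverage accounting.
#' @param norm_params a [normalization_params()].
#' @param marker_path marker catalog YAML; `NULL` for the packaged default.
#' @param distance,linkage clustering parameters (see [hcluster()]).
#' @param reference reference group for the three-way contrast design.
#' @param fdr FDR level in (0, 1).
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, sim = simulation_config(),
                       counts_path = NULL, probes_path = NULL,
                       samples_path = NULL, rcc_paths = NULL,
                       gmt_path = NULL, pathway_gmt_path = NULL,
                       norm_params = normalization_params(),
                       marker_path = NULL,
                       distance = "euclidean", linkage = "average",
                       reference = "EGFR/ERBB2wt", fdr = 0.05, seed = 1L) {
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)", call. = FALSE)
  if (is.null(sim)) {
    if (is.null(samples_path)) stop("samples_path required without a simulation",
                                    call. = FALSE)
    paths <- c(counts_path, probes_path, samples_path, rcc_paths)
    miss <- paths[!file.exists(paths)]
    if (length(miss) > 0) stop("input file(s) not found: ",
                               paste(miss, collapse = ", "), call. = FALSE)
  }
  for (p in c(gmt_path, pathway_gmt_path))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p, call. = FALSE)
  structure(list(out_dir = out_dir, sim = sim, counts_path = counts_path,
                 probes_path = probes_path, samples_path = samples_path,
                 rcc_paths = rcc_paths, gmt_path = gmt_path,
                 pathway_gmt_path = pathway_gmt_path, norm_params = norm_params,
                 marker_path = marker_path, distance = distance,
                 linkage = linkage, reference = reference, fdr = fdr,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate/load -> normalize -> score -> cluster (hot/cold) -> association
#' tests -> differential expression (genes and cell scores) -> Venn
#' partition of the three reference contrasts -> optional category
#' enrichment and pathway coverage. Every stage's table is written as TSV
#' under `config$out_dir`, plus a machine-readable `run_summary.json`.
#'
#' @param config a [run_config()].
#' @return invisibly, the run summary list.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  summary <- list(package_version = as.character(utils::packageVersion("immunopanel")),
                  seed = config$seed, fdr = config$fdr,
                  reference = config$reference,
                  timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  warnings = character(0))
  note <- function(w) summary$warnings <<- c(summary$warnings, w)

  # --- cohort -------------------------------------------------------------
  if (!is.null(config$sim)) {
    cfg <- config$sim
    cfg$seed <- config$seed
    sim <- simulate_cohort(cfg)
    counts <- sim$counts; probes <- sim$probes; samples <- sim$samples
    write_cohort(sim, config$out_dir)
  } else if (!is.null(config$rcc_paths)) {
    parsed <- read_rcc(config$rcc_paths)
    counts <- parsed$counts; probes <- parsed$probes
    samples <- read_samples(config$samples_path)
  } else {
    parsed <- read_counts(config$counts_path, config$probes_path)
    counts <- parsed$counts; probes <- parsed$probes
    samples <- read_samples(config$samples_path)
  }
  if (!all(colnames(counts) %in% samples$sample_id))
    stop_io("samples without group annotation: ",
            paste(setdiff(colnames(counts), samples$sample_id), collapse = ", "))
  if (!config$reference %in% samples$group)
    stop_io("reference group '", config$reference, "' absent from annotation")
  summary$n_samples <- ncol(counts)
  summary$n_probes <- nrow(counts)
  summary$groups <- as.list(table(samples$group))

  # --- normalize ----------------------------------------------------------
  norm <- normalize_counts(counts, probes, config$norm_params)
  write_tsv(norm, out("normalized.tsv"))
  summary$n_endogenous <- nrow(norm)

  # --- immune scores ------------------------------------------------------
  catalog <- read_marker_catalog(config$marker_path)
  scores <- withCallingHandlers(
    score_matrix(norm, catalog),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  write_tsv(scores, out("cell_scores.tsv"), id_col = "population")

  # --- hot/cold clustering ------------------------------------------------
  pop_scores <- scores[names(catalog), , drop = FALSE]
  cl <- hcluster(pop_scores, axis = "columns", k = 2,
                 distance = config$distance, linkage = config$linkage)
  hotcold <- label_hot_cold(cl, scores["total_TILs", ])
  write_tsv(data.frame(sample_id = names(hotcold),
                       cluster = unname(cl$cluster[names(hotcold)]),
                       state = unname(hotcold), stringsAsFactors = FALSE),
            out("clusters.tsv"))
  summary$n_hot <- sum(hotcold == "hot")
  summary$n_cold <- sum(hotcold == "cold")

  # --- cluster-vs-genotype association ------------------------------------
  grp <- align_groups(samples, colnames(norm))
  assoc <- list(all_groups = association_test(cross_table(hotcold, grp)))
  for (g in setdiff(unique(grp), config$reference)) {
    keep <- grp %in% c(g, config$reference)
    assoc[[paste0(g, ".vs.", config$reference)]] <-
      association_test(cross_table(hotcold[keep], grp[keep]))
  }
  assoc_df <- data.frame(contrast = names(assoc),
                         p = vapply(assoc, `[[`, numeric(1), "p.value"),
                         method = vapply(assoc, `[[`, character(1), "method"),
                         stringsAsFactors = FALSE, row.names = NULL)
  write_tsv(assoc_df, out("cluster_association.tsv"))

  # --- differential expression: genes and cell populations ----------------
  de_genes <- de_table(norm, samples, fdr = config$fdr)
  write_tsv(de_genes, out("de_genes.tsv"))
  de_cells <- de_table(scores, samples, fdr = config$fdr)
  write_tsv(de_cells, out("de_cell_scores.tsv"))
  summary$n_omnibus_significant <- sum(de_genes$kw_sig)
  summary$n_cell_populations_significant <-
    sum(de_cells$kw_sig[de_cells$feature %in% names(catalog)])

  # --- Venn partition of the three contrasts vs the reference -------------
  others <- setdiff(unique(grp), config$reference)
  venn_rows <- list()
  if (length(others) == 3) {
    for (direction in c("up", "down")) {
      sets <- lapply(others, function(g)
        significant_set(de_genes, c(g, config$reference), direction))
      vp <- venn_partition(sets[[1]], sets[[2]], sets[[3]], names = others)
      venn_rows[[direction]] <- data.frame(
        direction = direction, cell = names(vp),
        n = lengths(vp),
        genes = vapply(vp, paste, character(1), collapse = ","),
        stringsAsFactors = FALSE, row.names = NULL)
    }
    venn_df <- do.call(rbind, venn_rows)
    write_tsv(venn_df, out("venn.tsv"))
    summary$venn_cells <- stats::setNames(as.list(venn_df$n),
                                          paste(venn_df$direction, venn_df$cell,
                                                sep = ":"))
  } else {
    note("Venn partition skipped: design does not have 3 non-reference groups")
  }

  # --- enrichment / coverage ----------------------------------------------
  if (!is.null(config$gmt_path)) {
    catal <- read_gmt(config$gmt_path)
    sig_any <- de_genes$feature[de_genes$kw_sig]
    enr <- withCallingHandlers(
      enrich(sig_any, de_genes$feature, catal),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    write_tsv(enr, out("enrichment.tsv"))
  }
  if (!is.null(config$pathway_gmt_path)) {
    pw <- read_gmt(config$pathway_gmt_path)
    de_sets <- stats::setNames(lapply(others, function(g)
      significant_set(de_genes, c(g, config$reference))), others)
    cov_rows <- lapply(names(pw), function(nm) {
      cv <- pathway_coverage(pw[[nm]], de_genes$feature, de_sets, pathway = nm)
      data.frame(pathway = nm, n_annotated = cv$n_annotated,
                 n_covered = cv$n_covered,
                 coverage_percent = cv$coverage_percent,
                 n_de_total = cv$n_de_total,
                 de_percent_of_covered = cv$de_percent_of_covered,
                 stringsAsFactors = FALSE)
    })
    write_tsv(do.call(rbind, cov_rows), out("pathway_coverage.tsv"))
  }

  jsonlite::write_json(summary, out("run_summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(summary)
}

#' Validate a run summary against the packaged contract
#'
#' Checks that a summary (as written by [run_all()] to `run_summary.json`)
#' carries every required field with the right type.
#'
#' @param summary list, e.g. `jsonlite::read_json(...)`.
#' @return TRUE invisibly; errors listing missing/invalid fields otherwise.
#' @export
validate_run_summary <- function(summary) {
  required <- c(package_version = "character", seed = "numeric",
                fdr = "numeric", reference = "character",
                timestamp = "character", n_samples = "numeric",
                n_probes = "numeric", n_endogenous = "numeric",
                n_hot = "numeric", n_cold = "numeric",
                n_omnibus_significant = "numeric")
  problems <- character(0)
  for (f in names(required)) {
    if (is.null(summary[[f]])) { problems <- c(problems, paste0("missing: ", f)); next }
    v <- summary[[f]]
    ok <- switch(required[[f]],
                 character = is.character(v) && length(v) == 1,
                 numeric = is.numeric(v) && length(v) == 1)
    if (!ok) problems <- c(problems, paste0("invalid type: ", f))
  }
  if (length(problems) > 0)
    stop("run summary fails validation: ", paste(problems, collapse = "; "),
         call. = FALSE)
  invisible(TRUE)
}

#' Hot/cold score heatmap
#'
#' Row-centered immune-score heatmap with a blue (below row mean) to yellow
#' (above row mean) palette; requires the pheatmap package.
#'
#' @param scores populations x samples matrix.
#' @param annotation optional data.frame of per-sample annotations
#'   (rownames = sample ids).
#' @param filename optional output file (png/pdf as supported by pheatmap).
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plot_score_heatmap <- function(scores, annotation = NULL, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_score_heatmap requires the pheatmap package", call. = FALSE)
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#FFD92F"))(101)
  ph <- pheatmap::pheatmap(center_rows(scores), color = pal,
                           clustering_method = "average",
                           annotation_col = annotation, filename = filename,
                           silent = !is.na(filename), ...)
  invisible(ph)
}
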