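#' Fisher-exact over-representation of gene categories
#'
#' One two-sided Fisher exact test per category on the 2x2 table
#' (in category / not) x (significant / not), with the universe restricted
#' to the supplied panel genes: categories are intersected with the universe
#' before testing and skipped (with a warning) when the intersection is
#' empty. Both enrichment and depletion are reported through the same
#' two-sided p, with the direction read off the odds ratio. BH adjustment is
#' applied across the tested categories.
#'
#' @param sig character vector of significant genes; must be a subset of
#'   `universe`.
#' @param universe character vector of all tested genes (the panel).
#' @param catalog named list of gene sets (see [read_gmt()]).
#' @return data.frame: `category`, the four 2x2 cells (`sig_in`, `sig_out`,
#'   `nonsig_in`, `nonsig_out`), `odds_ratio`, `direction`, `p`, `p_adj`.
#' @export
enrich <- function(sig, universe, catalog) {
  universe <- unique(universe)
  sig <- unique(sig)
  bad <- setdiff(sig, universe)
  if (length(bad) > 0)
    stop("significant genes outside the universe: ",
         paste(bad, collapse = ", "), call. = FALSE)
  rows <- lapply(names(catalog), function(nm) {
    set <- intersect(unique(catalog[[nm]]), universe)
    if (length(set) == 0) {
      warning("category '", nm, "' has no overlap with the universe; skipped",
              call. = FALSE)
      return(NULL)
    }
    a <- length(intersect(sig, set))                 # sig & in set
    b <- length(sig) - a                             # sig & out
    c_ <- length(set) - a                            # non-sig & in set
    d <- length(universe) - a - b - c_               # non-sig & out
    tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    res <- association_test(tab)
    or <- (a * d) / (b * c_)
    data.frame(category = nm, sig_in = a, sig_out = b, nonsig_in = c_,
               nonsig_out = d, odds_ratio = or,
               direction = if (is.nan(or) || or >= 1) "enriched" else "depleted",
               p = res$p.value, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no category overlaps the universe", call. = FALSE)
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out
}

#' Pathway coverage and differential-expression accounting
#'
#' How much of an externally annotated pathway the targeted panel covers,
#' and how many covered genes are differentially expressed in each
#' comparison. Fractions are also reported as whole-number percentages
#' (`round(100 * fraction)`).
#'
#' @param pathway_genes character vector of genes annotated to the pathway.
#' @param panel_genes character vector of panel (universe) genes.
#' @param de_sets named list comparison -> significant gene set.
#' @param pathway name used in the report.
#' @return list with `pathway`, `n_annotated`, `n_covered`,
#'   `coverage_fraction`, `coverage_percent`, `de_fraction_of_covered`,
#'   `de_percent_of_covered`, `n_de_total` (union over comparisons) and
#'   `per_comparison` (data.frame `comparison`, `n_de`, `genes`).
#' @export
pathway_coverage <- function(pathway_genes, panel_genes,
                             de_sets = list(), pathway = "pathway") {
  pathway_genes <- unique(pathway_genes)
  covered <- intersect(pathway_genes, unique(panel_genes))
  per <- data.frame(
    comparison = names(de_sets),
    n_de = vapply(de_sets, function(s) length(intersect(s, covered)), integer(1)),
    genes = vapply(de_sets, function(s)
      paste(sort(intersect(s, covered)), collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  de_union <- unique(unlist(lapply(de_sets, intersect, x = covered)))
  cov_frac <- if (length(pathway_genes) > 0) length(covered) / length(pathway_genes) else 0
  de_frac <- if (length(covered) > 0) length(de_union) / length(covered) else 0
  list(pathway = pathway,
       n_annotated = length(pathway_genes),
       n_covered = length(covered),
       coverage_fraction = cov_frac,
       coverage_percent = round(100 * cov_frac),
       n_de_total = length(de_union),
       de_fraction_of_covered = de_frac,
       de_percent_of_covered = round(100 * de_frac),
       per_comparison = per)
}
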