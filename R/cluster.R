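#' Center matrix rows
#'
#' Subtracts each row's mean — the centering behind mean-anchored diverging
#' heatmaps (values above the row mean vs below it). Idempotent.
#'
#' @param m numeric matrix.
#' @return matrix of the same shape with row means 0.
#' @export
center_rows <- function(m) {
  stopifnot(is.matrix(m), nrow(m) > 0, ncol(m) > 0)
  sweep(m, 1, rowMeans(m), `-`)
}

#' Agglomerative clustering of rows or columns
#'
#' Hierarchical clustering (via [stats::hclust()]) of the chosen axis, with
#' the tree cut into exactly `k` clusters. Defaults — Euclidean distance on
#' row-centered values, average linkage — are the common expression-heatmap
#' convention; both are configurable. Cluster labels are `C1..Ck` numbered
#' by first appearance in input order, so the output is deterministic and
#' permutation-stable up to relabeling.
#'
#' @param m numeric matrix.
#' @param axis `"columns"` (cluster samples; default) or `"rows"`.
#' @param k number of clusters to cut.
#' @param distance distance measure for [stats::dist()] (default
#'   `"euclidean"`) or `"correlation"` for 1 - Pearson.
#' @param linkage agglomeration method for [stats::hclust()].
#' @param center center rows before computing distances (default TRUE).
#' @return list with `cluster` (named vector item -> label), `tree` (the
#'   hclust object) and `method` metadata.
#' @export
hcluster <- function(m, axis = c("columns", "rows"), k = 2,
                     distance = "euclidean", linkage = "average",
                     center = TRUE) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(m), all(is.finite(m)))
  if (center) m <- center_rows(m)
  x <- if (axis == "columns") t(m) else m
  if (k < 1 || k > nrow(x))
    stop("k must lie in [1, ", nrow(x), "]", call. = FALSE)
  d <- if (identical(distance, "correlation"))
    stats::as.dist(1 - stats::cor(t(x))) else stats::dist(x, method = distance)
  tree <- stats::hclust(d, method = linkage)
  raw <- stats::cutree(tree, k = k)
  relab <- stats::setNames(seq_len(k), unique(raw))   # number by first appearance
  cl <- stats::setNames(paste0("C", relab[as.character(raw)]), names(raw))
  list(cluster = cl, tree = tree,
       method = list(axis = axis, distance = distance, linkage = linkage,
                     k = k, centered = center))
}

#' Label a two-cluster sample partition as hot/cold
#'
#' The cluster with the higher mean total-TIL score is labeled `hot`, the
#' other `cold`. On an exact tie the larger cluster is labeled `cold` (an
#' arbitrary, documented convention) with a warning.
#'
#' @param assign result of [hcluster()] with k = 2 on samples.
#' @param total_til named per-sample total-TIL score vector.
#' @return named character vector sample -> `"hot"`/`"cold"`.
#' @export
label_hot_cold <- function(assign, total_til) {
  cl <- assign$cluster
  if (length(unique(cl)) != 2)
    stop("hot/cold labeling needs a k = 2 assignment", call. = FALSE)
  if (!all(names(cl) %in% names(total_til)))
    stop("total-TIL scores missing for some samples", call. = FALSE)
  means <- tapply(total_til[names(cl)], cl, mean)
  if (means[1] == means[2]) {
    warning("exact tie in cluster mean total-TIL; labeling larger cluster cold",
            call. = FALSE)
    sizes <- table(cl)
    cold <- names(sizes)[which.max(sizes)]
  } else {
    cold <- names(means)[which.min(means)]
  }
  stats::setNames(ifelse(cl == cold, "cold", "hot"), names(cl))
}

#' Exact association test on a contingency table
#'
#' Two-sided Fisher exact test (sum of table probabilities no larger than
#' the observed table's, for 2x2; the network-algorithm equivalent for
#' r x c). Degenerate margins (an all-zero row or column) return p = 1 with
#' a warning. For r x c tables with total N above `exact_limit`, an exact
#' enumeration is not attempted: the p-value is estimated by Monte-Carlo
#' simulation (1e5 tables, fixed internal seed) and flagged in the result.
#'
#' @param table matrix of nonnegative integer counts, at least 2x2.
#' @param exact_limit largest total N for which an exact r x c test is run
#'   (2x2 tables are always exact).
#' @return list with `p.value`, `method` (`"exact"` or `"monte-carlo"`) and
#'   the input `table`.
#' @export
association_test <- function(table, exact_limit = 200) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("association test needs at least a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("table entries must be nonnegative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("degenerate margin (all-zero row or column); p = 1", call. = FALSE)
    return(list(p.value = 1.0, method = "degenerate", table = table))
  }
  is2x2 <- nrow(table) == 2 && ncol(table) == 2
  if (is2x2 || sum(table) <= exact_limit) {
    p <- stats::fisher.test(table, workspace = 2e7)$p.value
    method <- "exact"
  } else {
    p <- withr::with_seed(20211, stats::fisher.test(table, simulate.p.value = TRUE,
                                                    B = 1e5)$p.value)
    method <- "monte-carlo"
  }
  list(p.value = min(p, 1.0), method = method, table = table)
}

#' Cross-tabulate two sample labelings
#'
#' @param a,b named vectors of labels over the same samples (e.g. hot/cold
#'   state vs mutation group).
#' @return contingency table (matrix) with `a` levels as rows.
#' @export
cross_table <- function(a, b) {
  common <- intersect(names(a), names(b))
  if (length(common) == 0) stop("no shared samples to tabulate", call. = FALSE)
  as.matrix(table(a[common], b[common]))
}
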