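#' Kruskal-Wallis omnibus test
#'
#' Rank-based omnibus test across all groups (tie-corrected H statistic,
#' chi-squared reference with groups - 1 degrees of freedom), computed by
#' [stats::kruskal.test()]. Every group must contribute at least 2 samples.
#'
#' @param values per-sample numeric vector (named or aligned to `groups`).
#' @param groups factor or character vector of group labels.
#' @return list with `statistic` (H) and `p.value`.
#' @export
kruskal_omnibus <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  check_group_sizes(groups)
  kw_stat(values, groups)
}

kw_stat <- function(values, gf) {
  if (length(unique(values)) == 1)
    return(list(statistic = 0, p.value = 1))   # complete ties
  kt <- stats::kruskal.test(values, gf)
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Pairwise Wilcoxon rank-sum post-hoc tests
#'
#' Two-sided rank-sum test per requested group pair. The exact distribution
#' is used when the combined sample size is 25 or less and there are no
#' ties; otherwise the normal approximation with continuity correction
#' (the switch is deterministic and recorded per pair).
#'
#' @param values per-sample numeric vector.
#' @param groups group labels aligned to `values`.
#' @param pairs list of 2-element character vectors (group pairs).
#' @return data.frame with `group_a`, `group_b`, `p`, `exact`.
#' @export
pairwise_wilcoxon <- function(values, groups, pairs) {
  groups <- as.character(groups)
  out <- lapply(pairs, function(pr) {
    x <- values[groups == pr[1]]
    y <- values[groups == pr[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("pair ", pr[1], " vs ", pr[2], ": both groups need >= 2 samples",
           call. = FALSE)
    exact <- (length(x) + length(y) <= 25) && !anyDuplicated(c(x, y))
    if (length(unique(c(x, y))) == 1) {
      # complete ties: no evidence either way
      return(data.frame(group_a = pr[1], group_b = pr[2], p = 1.0,
                        exact = FALSE, stringsAsFactors = FALSE))
    }
    wt <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
    data.frame(group_a = pr[1], group_b = pr[2], p = wt$p.value,
               exact = exact, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]): the adjusted value of
#' the i-th smallest p is `min_{j >= i} m p_(j) / j`, capped at 1.
#'
#' @param pvals numeric vector of p-values in [0, 1] (NA allowed,
#'   propagated).
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Signed fold change from log2 group means
#'
#' Linear-scale ratio `r = 2^(meanA - meanB)`, reported as `r` when at least
#' 1 and as `-1/r` otherwise (negative = lower in A). Antisymmetric under
#' swapping the groups except at equality, where it is +1.
#'
#' @param meanA,meanB log2-scale group means.
#' @return signed linear fold change.
#' @export
signed_fold_change <- function(meanA, meanB) {
  r <- 2^(meanA - meanB)
  ifelse(r >= 1, r, -1 / r)
}

#' Per-feature differential expression table
#'
#' For every row of `mat` (genes, or immune-cell score rows — the identical
#' machinery serves both): group means of the log2 values, the
#' Kruskal-Wallis omnibus H and p with BH adjustment across features, and,
#' per requested group pair, the two-sided Wilcoxon p (BH-adjusted across
#' features within that pair's family), the signed fold change of group
#' means, and a significance flag at the requested FDR. With
#' `gate_on_omnibus = TRUE` (default) a pairwise flag additionally requires
#' omnibus significance, mirroring an omnibus-gated post-hoc design.
#'
#' @param mat features x samples log2 matrix.
#' @param samples data.frame with `sample_id`, `group` covering `colnames(mat)`.
#' @param pairs list of group pairs to contrast; default all unordered pairs.
#' @param fdr FDR level for significance flags (default 0.05).
#' @param gate_on_omnibus require omnibus significance for pairwise flags.
#' @return data.frame, one row per feature: `feature`, `mean_<group>` per
#'   group, `kw_H`, `kw_p`, `kw_p_adj`, `kw_sig`, then per pair
#'   `p_<A.vs.B>`, `p_adj_<A.vs.B>`, `fc_<A.vs.B>`, `sig_<A.vs.B>`.
#' @export
de_table <- function(mat, samples, pairs = NULL, fdr = 0.05,
                     gate_on_omnibus = TRUE) {
  stopifnot(is.matrix(mat))
  grp <- align_groups(samples, colnames(mat))
  glev <- unique(grp)
  check_group_sizes(factor(grp))
  if (is.null(pairs))
    pairs <- utils::combn(glev, 2, simplify = FALSE)
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)", call. = FALSE)

  means <- vapply(glev, function(g) rowMeans(mat[, grp == g, drop = FALSE]),
                  numeric(nrow(mat)))
  gf <- factor(grp)
  kw <- apply(mat, 1, function(v) {
    kt <- kw_stat(v, gf)
    c(kt$statistic, kt$p.value)
  })
  out <- data.frame(feature = rownames(mat), stringsAsFactors = FALSE)
  for (g in glev) out[[paste0("mean_", g)]] <- means[, g]
  out$kw_H <- kw[1, ]
  out$kw_p <- kw[2, ]
  out$kw_p_adj <- bh_adjust(out$kw_p)
  out$kw_sig <- out$kw_p_adj < fdr

  for (pr in pairs) {
    tag <- paste0(pr[1], ".vs.", pr[2])
    pw <- apply(mat, 1, function(v)
      pairwise_wilcoxon(v, grp, list(pr))$p)
    padj <- bh_adjust(pw)
    fc <- signed_fold_change(means[, pr[1]], means[, pr[2]])
    sig <- padj < fdr
    if (gate_on_omnibus) sig <- sig & out$kw_sig
    out[[paste0("p_", tag)]] <- pw
    out[[paste0("p_adj_", tag)]] <- padj
    out[[paste0("fc_", tag)]] <- fc
    out[[paste0("sig_", tag)]] <- sig
  }
  attr(out, "pairs") <- pairs
  attr(out, "fdr") <- fdr
  out
}

#' Extract significant gene sets from a DE table
#'
#' @param de result of [de_table()].
#' @param pair 2-element character vector naming the contrast.
#' @param direction `"up"` (fold change > 0 in A vs B), `"down"`, or
#'   `"both"`.
#' @return character vector of feature ids.
#' @export
significant_set <- function(de, pair, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  tag <- paste0(pair[1], ".vs.", pair[2])
  sig_col <- paste0("sig_", tag)
  fc_col <- paste0("fc_", tag)
  if (!sig_col %in% colnames(de))
    stop("contrast ", tag, " not present in DE table", call. = FALSE)
  keep <- de[[sig_col]]
  if (direction == "up") keep <- keep & de[[fc_col]] > 1
  if (direction == "down") keep <- keep & de[[fc_col]] < -1
  de$feature[keep]
}

#' Three-set Venn partition
#'
#' Decomposes three significant-gene sets (e.g. the three mutated groups
#' each contrasted with wild type) into the seven disjoint Venn cells:
#' exclusive to each set, each pairwise-only overlap, and the triple
#' overlap. Cells are pairwise disjoint and their union is the union of the
#' inputs.
#'
#' @param sigA,sigB,sigC character vectors (gene sets).
#' @param names length-3 labels for the sets.
#' @return named list of 7 character vectors: `A_only`, `B_only`, `C_only`,
#'   `AB_only`, `AC_only`, `BC_only`, `ABC` (names built from `names`).
#' @export
venn_partition <- function(sigA, sigB, sigC, names = c("A", "B", "C")) {
  sigA <- unique(sigA); sigB <- unique(sigB); sigC <- unique(sigC)
  inA <- function(g) g %in% sigA
  inB <- function(g) g %in% sigB
  inC <- function(g) g %in% sigC
  u <- union(union(sigA, sigB), sigC)
  key <- paste0(as.integer(inA(u)), as.integer(inB(u)), as.integer(inC(u)))
  cells <- list(
    "100" = paste0(names[1], "_only"), "010" = paste0(names[2], "_only"),
    "001" = paste0(names[3], "_only"),
    "110" = paste0(names[1], ".", names[2], "_only"),
    "101" = paste0(names[1], ".", names[3], "_only"),
    "011" = paste0(names[2], ".", names[3], "_only"),
    "111" = paste(names, collapse = "."))
  out <- stats::setNames(vector("list", 7), unlist(cells))
  for (k in names(cells)) out[[cells[[k]]]] <- sort(u[key == k])
  out
}

#' Align group labels to a sample ordering
#'
#' @param samples data.frame with `sample_id` and `group`.
#' @param sample_ids character vector (e.g. matrix column names).
#' @return named character vector sample_id -> group, in `sample_ids` order.
#' @export
align_groups <- function(samples, sample_ids) {
  if (!all(c("sample_id", "group") %in% colnames(samples)))
    stop("sample annotation needs sample_id and group columns", call. = FALSE)
  idx <- match(sample_ids, samples$sample_id)
  if (anyNA(idx))
    stop("samples missing from annotation: ",
         paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  stats::setNames(samples$group[idx], sample_ids)
}

check_group_sizes <- function(groups) {
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tab < 2))
    stop("group(s) with < 2 samples: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
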