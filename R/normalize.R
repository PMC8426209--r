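#' Geometric mean
#'
#' @param values numeric vector of strictly positive values.
#' @return `exp(mean(log(values)))`.
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0) stop("geometric_mean of empty vector", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("geometric_mean requires finite positive values", call. = FALSE)
  exp(mean(log(values)))
}

#' Normalization parameters
#'
#' The standard nCounter workflow: positive-control scaling, negative-control
#' background flooring, housekeeping geometric-mean scaling, then
#' `log2(x + pseudocount)`. Each step can be switched off to match
#' alternative conventions.
#'
#' @param use_positive_controls scale each sample by the grand geometric
#'   mean of positive-control counts over its own positive-control geomean.
#' @param background_mode `"threshold_mean_plus_2sd"` floors endogenous and
#'   housekeeping counts at mean + 2 SD of the sample's negative controls;
#'   `"none"` disables.
#' @param housekeeping_mode `"geomean_scale"` equalizes per-sample
#'   housekeeping geometric means; `"none"` disables.
#' @param pseudocount added before the log2 transform (default 1, bounded
#'   behavior at zero counts).
#' @return a `normalization_params` list.
#' @export
normalization_params <- function(use_positive_controls = TRUE,
                                 background_mode = c("threshold_mean_plus_2sd", "none"),
                                 housekeeping_mode = c("geomean_scale", "none"),
                                 pseudocount = 1.0) {
  background_mode <- match.arg(background_mode)
  housekeeping_mode <- match.arg(housekeeping_mode)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("pseudocount must be a single positive number", call. = FALSE)
  structure(list(use_positive_controls = isTRUE(use_positive_controls),
                 background_mode = background_mode,
                 housekeeping_mode = housekeeping_mode,
                 pseudocount = pseudocount),
            class = "normalization_params")
}

#' Normalize panel counts to log2 expression
#'
#' Per sample, in order: (1) positive-control scaling; (2) background
#' flooring at mean + 2 SD of the sample's negative controls; (3)
#' housekeeping geometric-mean scaling; (4) `log2(x + pseudocount)`.
#' Control probes are dropped from the output, which contains exactly the
#' endogenous genes in input order.
#'
#' @param counts genes x samples count matrix (rownames = gene ids).
#' @param probes probe annotation (`gene_id`, `probe_class`) aligned to
#'   `counts` rows.
#' @param params a [normalization_params()] object.
#' @return numeric matrix, endogenous genes x samples, log2 scale. The
#'   per-sample housekeeping scale factors are attached as
#'   `attr(, "hk_factors")`.
#' @export
normalize_counts <- function(counts, probes, params = normalization_params()) {
  stopifnot(inherits(params, "normalization_params"))
  validate_counts(counts, probes)
  cls <- probes$probe_class
  x <- counts * 1.0

  if (params$housekeeping_mode == "geomean_scale") {
    hk_raw <- counts[cls == "housekeeping", , drop = FALSE]
    if (nrow(hk_raw) == 0) stop_io("housekeeping scaling requested but no housekeeping probes")
    zero <- colSums(hk_raw) == 0
    if (any(zero))
      stop_io("all-zero housekeeping counts in sample(s): ",
              paste(colnames(counts)[zero], collapse = ", "))
  }

  if (params$use_positive_controls) {
    pos <- x[cls == "positive_control", , drop = FALSE]
    if (nrow(pos) == 0) stop_io("positive-control scaling requested but no positive_control probes")
    gm <- apply(pos + ifelse(any(pos == 0), 0.5, 0), 2, geometric_mean)
    x <- sweep(x, 2, geometric_mean(gm) / gm, `*`)
  }

  if (params$background_mode == "threshold_mean_plus_2sd") {
    neg <- x[cls == "negative_control", , drop = FALSE]
    if (nrow(neg) == 0) stop_io("background thresholding requested but no negative_control probes")
    thr <- apply(neg, 2, function(v) mean(v) + 2 * stats::sd(v))
    keep <- cls %in% c("endogenous", "housekeeping")
    x[keep, ] <- pmax(x[keep, , drop = FALSE],
                      matrix(thr, nrow = sum(keep), ncol = ncol(x), byrow = TRUE))
  }

  hk_factors <- rep(1.0, ncol(x))
  if (params$housekeeping_mode == "geomean_scale") {
    hk <- x[cls == "housekeeping", , drop = FALSE]
    gm <- apply(hk + ifelse(any(hk == 0), 0.5, 0), 2, geometric_mean)
    hk_factors <- geometric_mean(gm) / gm
    x <- sweep(x, 2, hk_factors, `*`)
  }

  out <- log2(x[cls == "endogenous", , drop = FALSE] + params$pseudocount)
  attr(out, "hk_factors") <- hk_factors
  out
}
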