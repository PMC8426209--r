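#' Marker-mean immune cell score
#'
#' The relative abundance of an immune population is the arithmetic mean of
#' its marker genes' log2 normalized expression (the geometric mean on the
#' linear scale) — the marker-mean construction of Danaher-style cell
#' scoring. Markers absent from the matrix are dropped with a warning that
#' lists them; a population with no marker present is an error.
#'
#' @param norm normalized log2 matrix, genes x samples.
#' @param markers character vector of marker symbols.
#' @param population optional population name used in messages.
#' @return named numeric vector, one score per sample.
#' @export
cell_score <- function(norm, markers, population = NULL) {
  lab <- if (is.null(population)) "marker set" else paste0("population '", population, "'")
  present <- intersect(markers, rownames(norm))
  if (length(present) == 0)
    stop(lab, ": none of the markers (", paste(markers, collapse = ", "),
         ") are present in the matrix", call. = FALSE)
  absent <- setdiff(markers, present)
  if (length(absent) > 0)
    warning(lab, ": dropping absent marker(s) ", paste(absent, collapse = ", "),
            call. = FALSE)
  colMeans(norm[present, , drop = FALSE])
}

#' Score all populations of a marker catalog
#'
#' @param norm normalized log2 matrix, genes x samples.
#' @param catalog named list of marker vectors (see [read_marker_catalog()]).
#' @param total_til_subset population names entering the total-TIL composite
#'   (default: all populations in the catalog).
#' @return matrix with one row per population plus `total_TILs` and
#'   `cytolytic_activity`, columns = samples.
#' @export
score_matrix <- function(norm, catalog = read_marker_catalog(),
                         total_til_subset = names(catalog)) {
  scores <- t(vapply(names(catalog),
                     function(p) cell_score(norm, catalog[[p]], p),
                     numeric(ncol(norm))))
  colnames(scores) <- colnames(norm)
  out <- rbind(scores,
               total_TILs = total_til_score(scores, total_til_subset),
               cytolytic_activity = cytolytic_activity(norm))
  out
}

#' Total tumor-infiltrating lymphocyte score
#'
#' Arithmetic mean of a configurable subset of population scores (default:
#' all rows of the score matrix). The exact population subset entering the
#' published total-TIL composite is a modeling choice; the default uses all
#' populations and is documented as such.
#'
#' @param scores populations x samples score matrix.
#' @param subset population names to average.
#' @return named numeric vector, one value per sample.
#' @export
total_til_score <- function(scores, subset = rownames(scores)) {
  if (length(subset) == 0) stop("total-TIL subset is empty", call. = FALSE)
  missing <- setdiff(subset, rownames(scores))
  if (length(missing) > 0)
    stop("total-TIL subset not in score matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  colMeans(scores[subset, , drop = FALSE])
}

#' Cytolytic activity
#'
#' Mean of log2 granzyme A (GZMA) and perforin (PRF1) expression — a
#' granzyme/perforin proxy for killing capacity. Identical by construction
#' to `cell_score(norm, c("GZMA", "PRF1"))`, but both genes are required.
#'
#' @param norm normalized log2 matrix, genes x samples.
#' @return named numeric vector, one value per sample.
#' @export
cytolytic_activity <- function(norm) {
  missing <- setdiff(c("GZMA", "PRF1"), rownames(norm))
  if (length(missing) > 0)
    stop("cytolytic activity requires GZMA and PRF1; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  colMeans(norm[c("GZMA", "PRF1"), , drop = FALSE])
}
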