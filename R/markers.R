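#' Load a marker-set catalog
#'
#' Reads a YAML mapping of immune-cell population name to marker gene
#' symbols. With no argument, loads the packaged catalog of 14 populations
#' (B cells, CD45, CD56dim NK cells, CD8 T cells, cytotoxic cells, dendritic
#' cells, exhausted CD8 T cells, macrophages, mast cells, neutrophils, NK
#' cells, T cells, Th1 cells, Treg) following the published Danaher
#' signature resource.
#'
#' @param path YAML file; `NULL` for the packaged default.
#' @return named list of character marker vectors.
#' @export
read_marker_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "immune_markers.yaml", package = "immunopanel")
  if (!nzchar(path) || !file.exists(path)) stop_io("marker catalog not found: ", path)
  cat <- yaml::read_yaml(path)
  if (length(cat) == 0) stop_io("marker catalog is empty")
  for (nm in names(cat)) {
    m <- as.character(unlist(cat[[nm]]))
    if (length(m) == 0) stop_io("marker set '", nm, "' is empty")
    if (anyDuplicated(m)) stop_io("duplicate markers in set '", nm, "'")
    cat[[nm]] <- m
  }
  cat
}
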