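#' Read RCC (Reporter Code Count) files
#'
#' Parses the native per-sample nCounter export: comma-separated sections
#' tagged `<Header>`, `<Sample_Attributes>`, `<Lane_Attributes>` and
#' `<Code_Summary>` (columns `CodeClass,Name,Accession,Count`). One file is
#' one sample; the sample id is taken from the `ID` row of
#' `Sample_Attributes`, falling back to the file stem. CodeClass values map
#' Endogenous -> endogenous, Housekeeping -> housekeeping,
#' Positive -> positive_control, Negative -> negative_control; unknown
#' classes map to endogenous with a warning.
#'
#' @param paths character vector of RCC file paths.
#' @return list with `counts` (genes x samples integer matrix) and `probes`
#'   (data.frame `gene_id`, `probe_class`), as from [read_counts()].
#' @export
read_rcc <- function(paths) {
  if (length(paths) == 0) stop_io("no RCC files given")
  parsed <- lapply(paths, parse_rcc_one)
  ref <- parsed[[1]]
  for (p in parsed[-1]) {
    if (!identical(ref$probes$gene_id, p$probes$gene_id)) {
      d <- union(setdiff(ref$probes$gene_id, p$probes$gene_id),
                 setdiff(p$probes$gene_id, ref$probes$gene_id))
      if (length(d) > 0)
        stop_io("inconsistent probe sets across RCC files; mismatched probes: ",
                paste(sort(d), collapse = ", "))
      stop_io("RCC files list the same probes in different orders")
    }
  }
  ids <- vapply(parsed, `[[`, character(1), "sample_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) stop_io("duplicate RCC sample ids: ", paste(dup, collapse = ", "))
  counts <- vapply(parsed, `[[`, integer(nrow(ref$probes)), "counts")
  dimnames(counts) <- list(ref$probes$gene_id, ids)
  list(counts = counts, probes = ref$probes)
}

parse_rcc_one <- function(path) {
  if (!file.exists(path)) stop_io("RCC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sec <- rcc_sections(lines)
  if (is.null(sec$Code_Summary))
    stop_io("RCC file lacks <Code_Summary> section: ", path)
  sample_id <- rcc_sample_id(sec$Sample_Attributes, path)
  cs <- sec$Code_Summary
  header <- strsplit(cs[1], ",", fixed = TRUE)[[1]]
  need <- c("CodeClass", "Name", "Count")
  if (!all(need %in% header))
    stop_io("RCC <Code_Summary> header must contain CodeClass,Name,Count: ", path)
  rows <- strsplit(cs[-1], ",", fixed = TRUE)
  rows <- rows[lengths(rows) >= 3]
  get <- function(col) vapply(rows, function(r) trimws(r[match(col, header)]), character(1))
  name <- get("Name")
  cls <- rcc_map_class(get("CodeClass"), path)
  cnt <- suppressWarnings(as.numeric(get("Count")))
  if (anyNA(cnt) || any(cnt < 0))
    stop_io("non-numeric or negative Count in RCC file: ", path)
  dup <- unique(name[duplicated(name)])
  if (length(dup) > 0)
    stop_io("duplicate probe names in ", path, ": ", paste(dup, collapse = ", "))
  list(sample_id = sample_id, counts = as.integer(round(cnt)),
       probes = data.frame(gene_id = name, probe_class = cls,
                           stringsAsFactors = FALSE))
}

rcc_sections <- function(lines) {
  starts <- grep("^<[A-Za-z_]+>\\s*$", lines)
  ends <- grep("^</[A-Za-z_]+>\\s*$", lines)
  out <- list()
  for (s in starts) {
    tag <- sub("^<([A-Za-z_]+)>.*$", "\\1", lines[s])
    e <- ends[ends > s]
    e <- if (length(e)) min(e) else length(lines) + 1
    body <- lines[seq(s + 1, e - 1)]
    out[[tag]] <- body[nzchar(trimws(body))]
  }
  out
}

rcc_sample_id <- function(attrs, path) {
  if (!is.null(attrs)) {
    kv <- strsplit(attrs, ",", fixed = TRUE)
    for (r in kv) if (length(r) >= 2 && trimws(r[1]) == "ID" && nzchar(trimws(r[2])))
      return(trimws(r[2]))
  }
  tools::file_path_sans_ext(basename(path))
}

rcc_map_class <- function(cls, path) {
  map <- c(Endogenous = "endogenous", Housekeeping = "housekeeping",
           Positive = "positive_control", Negative = "negative_control")
  known <- cls %in% names(map)
  if (any(!known))
    warning("unknown CodeClass values in ", basename(path), " mapped to endogenous: ",
            paste(unique(cls[!known]), collapse = ", "), call. = FALSE)
  out <- unname(map[cls])
  out[!known] <- "endogenous"
  out
}

#' Write one RCC file per sample
#'
#' Emits the minimal Reporter Code Count dialect [read_rcc()] parses, so a
#' simulated cohort can be round-tripped through the native-format entry
#' point.
#'
#' @param counts genes x samples integer matrix.
#' @param probes probe annotation data.frame (`gene_id`, `probe_class`).
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_rcc <- function(counts, probes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inv <- c(endogenous = "Endogenous", housekeeping = "Housekeeping",
           positive_control = "Positive", negative_control = "Negative")
  paths <- character(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    sid <- colnames(counts)[j]
    lines <- c(
      "<Header>", "FileVersion,1.7", "SoftwareVersion,synthetic", "</Header>",
      "<Sample_Attributes>", paste0("ID,", sid), "</Sample_Attributes>",
      "<Lane_Attributes>", "ID,1", "</Lane_Attributes>",
      "<Code_Summary>", "CodeClass,Name,Accession,Count",
      paste(inv[probes$probe_class], probes$gene_id, "NA", counts[, j], sep = ","),
      "</Code_Summary>")
    paths[j] <- file.path(dir, paste0(sid, ".RCC"))
    writeLines(lines, paths[j])
  }
  invisible(paths)
}
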