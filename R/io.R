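#' @title Panel input/output
#' @description Readers and writers for the external artifacts the workflow
#'   touches: counts tables, probe and sample annotations, RCC files, GMT
#'   gene-set catalogs and result tables. All readers validate strictly and
#'   fail with messages that name the offending entries.
#' @name panel-io
NULL

PROBE_CLASSES <- c("endogenous", "housekeeping", "positive_control", "negative_control")

stop_io <- function(...) stop(..., call. = FALSE)

#' Read a counts table and its probe annotation
#'
#' The counts file is TSV or CSV (dialect sniffed from the extension and
#' first line) with gene rows, sample columns and a header row; the probe
#' table maps every gene to a probe class (`endogenous`, `housekeeping`,
#' `positive_control`, `negative_control`).
#'
#' @param path path to the counts TSV/CSV.
#' @param probe_path path to the probe annotation table with columns
#'   `gene_id` and `probe_class`.
#' @return a list with `counts` (integer matrix, genes x samples, with
#'   dimnames) and `probes` (data.frame `gene_id`, `probe_class`).
#' @export
read_counts <- function(path, probe_path) {
  counts <- read_counts_table(path)
  probes <- read_probe_annotation(probe_path)
  missing <- setdiff(rownames(counts), probes$gene_id)
  if (length(missing) > 0)
    stop_io("genes absent from probe annotation: ", paste(missing, collapse = ", "))
  probes <- probes[match(rownames(counts), probes$gene_id), , drop = FALSE]
  rownames(probes) <- NULL
  validate_counts(counts, probes)
  list(counts = counts, probes = probes)
}

read_counts_table <- function(path) {
  if (!file.exists(path)) stop_io("counts file not found: ", path)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"", comment.char = "")
  if (ncol(df) < 2) stop_io("counts file needs a gene column plus >= 1 sample column: ", path)
  genes <- trimws(df[[1]])
  samples <- colnames(df)[-1]
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g) > 0) stop_io("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s) > 0) stop_io("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop_io("invalid count '", vals[i, j], "' for gene ", genes[i],
            ", sample ", samples[j])
  }
  if (any(num != round(num)))
    warning("non-integer counts rounded to nearest integer", call. = FALSE)
  m <- matrix(as.integer(round(num)), nrow = length(genes),
              dimnames = list(genes, samples))
  m
}

read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop_io("probe annotation not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, colClasses = "character")
  need <- c("gene_id", "probe_class")
  if (!all(need %in% colnames(df)))
    stop_io("probe annotation must have columns gene_id, probe_class")
  df$gene_id <- trimws(df$gene_id)
  df$probe_class <- trimws(df$probe_class)
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup) > 0) stop_io("duplicate probe ids: ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(df$probe_class), PROBE_CLASSES)
  if (length(bad) > 0)
    stop_io("unknown probe_class values: ", paste(bad, collapse = ", "))
  df[, need]
}

validate_counts <- function(counts, probes) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop_io("negative counts present")
  if (!identical(rownames(counts), probes$gene_id))
    stop_io("counts rows and probe annotation out of sync")
  invisible(TRUE)
}

#' Read a sample annotation table
#'
#' @param path TSV/CSV with columns `sample_id` and `group` (additional
#'   covariate columns are kept).
#' @return data.frame with character `sample_id` and `group`.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop_io("sample annotation not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sniff_sep(path),
                          check.names = FALSE, colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop_io("sample annotation must have columns sample_id, group")
  df$sample_id <- trimws(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) stop_io("duplicate sample ids: ", paste(dup, collapse = ", "))
  df
}

#' Read a GMT gene-set catalog
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. Duplicate members within a set are dropped with a warning;
#' a line with fewer than three fields is an error.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors; set descriptions in
#'   `attr(, "description")`. File order preserved.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_io("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- trimws(f)
    f <- f[nzchar(f) | seq_along(f) <= 2]       # keep empty description field
    if (length(f) < 3)
      stop_io("GMT line ", i, " has no members: ", lines[[i]])
    name <- f[1]
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("GMT set '", name, "': duplicate members deduplicated", call. = FALSE)
      members <- unique(members)
    }
    if (name %in% names(sets)) stop_io("duplicate GMT set name: ", name)
    sets[[name]] <- members
    desc[name] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set catalog
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a data table as TSV (deterministic formatting)
#' @param df data.frame or matrix; matrices are written with a leading id
#'   column named by `id_col`.
#' @param path output path.
#' @param id_col name for the row-name column when writing a matrix.
#' @export
write_tsv <- function(df, path, id_col = "gene_id") {
  if (is.matrix(df)) {
    df <- data.frame(rownames(df), df, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- id_col
  }
  utils::write.table(format_df(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# fixed 15-significant-digit rendering so identical numbers always produce
# identical bytes on disk
format_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
  }
  df
}

sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) return(",")
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) return("\t")
  first <- readLines(path, n = 1)
  if (grepl("\t", first)) "\t" else ","
}
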