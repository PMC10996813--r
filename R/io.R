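# On-disk formats: TSV matrices (features in rows, samples in columns,
# first header cell "feature_id"), GMT gene-set libraries, and TSV tables
# for metadata, probe manifests, copy-number segments and mutations.
# Missing numerics are "NA" on disk and NA in memory.

#' Read a feature-by-sample matrix from TSV
#'
#' Expects a header row whose first cell is \code{feature_id} followed by
#' sample ids, and one row per feature.  Values are validated against
#' \code{value_kind} (FPKM non-negative, beta in [0,1]); violations are
#' reported with the offending feature and sample.
#'
#' @param path TSV file path.
#' @param value_kind one of \code{"fpkm"}, \code{"log2_expression"},
#'   \code{"beta"}, \code{"m_value"}.
#' @return an \code{\link{omics_matrix}}.
#' @export
read_matrix <- function(path, value_kind) {
  value_kind <- match.arg(value_kind, VALUE_KINDS)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop(sprintf("%s: matrix needs a feature column and >=1 sample", path),
                         call. = FALSE)
  fid <- as.character(df[[1]])
  if (anyDuplicated(fid)) {
    stop(sprintf("%s: duplicate feature id '%s'", path, fid[duplicated(fid)][1]),
         call. = FALSE)
  }
  sid <- colnames(df)[-1]
  if (anyDuplicated(sid)) {
    stop(sprintf("%s: duplicate sample id '%s'", path, sid[duplicated(sid)][1]),
         call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(sprintf("%s: non-numeric values in matrix body", path),
                           call. = FALSE)
  dimnames(m) <- list(fid, sid)
  tryCatch(omics_matrix(m, value_kind),
           error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                                    call. = FALSE))
}

#' Write a feature-by-sample matrix to TSV
#'
#' @param x an \code{\link{omics_matrix}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' Standard GMT: one set per line, tab-separated \code{name}, then
#' \code{description}, then gene ids.  Gene lists are deduplicated with
#' order preserved.
#'
#' @param path GMT file path.
#' @return a \code{\link{gene_set_library}}.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(gene_set_library(setNames(list(), character(0))))
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("%s: line %d has %d field(s); GMT needs name, description, genes...",
                   path, i, length(f)), call. = FALSE)
    }
    sets[[f[1]]] <- unique(f[-(1:2)])
    descs <- c(descs, f[2])
  }
  gene_set_library(sets, descriptions = descs)
}

#' Write a gene-set library to GMT
#' @param library a \code{\link{gene_set_library}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(names(library), function(nm) {
    paste(c(nm, library[[nm]]$description, library[[nm]]$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

read_table_checked <- function(path, required, label) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: %s missing required column(s): %s",
                 path, label, paste(miss, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read cohort metadata from TSV
#'
#' Required columns: sample_id, timepoint, survival_time, event.  Optional:
#' tumor_fraction, histology, cn_altered (\code{true}/\code{false}/
#' \code{unknown} or logical).  Unknown columns are preserved.
#'
#' @param path TSV file path.
#' @return a \code{\link{cohort_metadata}} data frame.
#' @export
read_metadata <- function(path) {
  df <- read_table_checked(path, c("sample_id", "timepoint", "survival_time", "event"),
                           "metadata")
  if (!is.null(df$cn_altered) && is.character(df$cn_altered)) {
    v <- tolower(df$cn_altered)
    df$cn_altered <- ifelse(v %in% c("true", "1"), TRUE,
                            ifelse(v %in% c("false", "0"), FALSE, NA))
  }
  tryCatch(cohort_metadata(df),
           error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                                    call. = FALSE))
}

#' Write cohort metadata to TSV
#' @param metadata a \code{\link{cohort_metadata}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  df <- as.data.frame(metadata)
  if (!is.null(df$cn_altered)) {
    df$cn_altered <- ifelse(is.na(df$cn_altered), "unknown",
                            ifelse(df$cn_altered, "true", "false"))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe manifest from TSV
#' @param path TSV with columns probe_id, chrom, position, gene,
#'   region_class, snp_vaf.
#' @return a \code{\link{probe_manifest}}.
#' @export
read_manifest <- function(path) {
  df <- read_table_checked(path, c("probe_id", "chrom", "position", "gene",
                                   "region_class", "snp_vaf"), "manifest")
  df$gene[is.na(df$gene)] <- ""
  tryCatch(probe_manifest(df),
           error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                                    call. = FALSE))
}

#' Write a probe manifest to TSV
#' @param manifest a \code{\link{probe_manifest}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.table(as.data.frame(manifest), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a SEG-like copy-number segment table from TSV
#'
#' Coordinates are 1-based inclusive, as emitted by segmentation tools.
#'
#' @param path TSV with columns sample_id, chrom, start, end, log2_ratio, call.
#' @return a \code{\link{segment_table}}.
#' @export
read_segments <- function(path) {
  df <- read_table_checked(path, c("sample_id", "chrom", "start", "end",
                                   "log2_ratio", "call"), "segment table")
  tryCatch(segment_table(df),
           error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                                    call. = FALSE))
}

#' Write a segment table to TSV
#' @param segments a \code{\link{segment_table}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_segments <- function(segments, path) {
  write.table(as.data.frame(segments), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a MAF-like mutation table from TSV
#' @param path TSV with columns sample_id, gene, protein_change,
#'   variant_class, vaf.
#' @return a \code{\link{mutation_table}}.
#' @export
read_mutations <- function(path) {
  df <- read_table_checked(path, c("sample_id", "gene", "protein_change",
                                   "variant_class", "vaf"), "mutation table")
  tryCatch(mutation_table(df),
           error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                                    call. = FALSE))
}

#' Write a mutation table to TSV
#' @param mutations a \code{\link{mutation_table}}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  write.table(as.data.frame(mutations), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
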