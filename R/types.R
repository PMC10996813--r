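# In-memory domain types.  All pipeline stages exchange these; on-disk
# formats live in io.R.

VALUE_KINDS <- c("fpkm", "log2_expression", "beta", "m_value")
REGION_CLASSES <- c("TSS", "five_prime_UTR", "first_exon", "gene_body",
                    "three_prime_UTR", "intergenic")
HISTOLOGIES <- c("common", "LH", "SCV", "unknown")

#' Feature-by-sample omics matrix
#'
#' The common currency of the pipeline: a dense numeric matrix of features
#' (genes or methylation probes) by samples, tagged with the kind of value
#' it holds so that downstream operations can enforce their scale
#' assumptions (FPKM is non-negative, beta lies in [0,1], clustering wants
#' log2 expression or M-values).
#'
#' @param values numeric matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids).
#' @param value_kind one of \code{"fpkm"}, \code{"log2_expression"},
#'   \code{"beta"}, \code{"m_value"}.
#' @return an object of class \code{omics_matrix}: a list with elements
#'   \code{values} and \code{value_kind}.
#' @export
omics_matrix <- function(values, value_kind) {
  value_kind <- match.arg(value_kind, VALUE_KINDS)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("`values` must have feature rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(fid)) {
    stop("duplicate feature ids: ", paste(unique(fid[duplicated(fid)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "),
         call. = FALSE)
  }
  check_value_range(values, value_kind)
  structure(list(values = values, value_kind = value_kind),
            class = "omics_matrix")
}

# range validation naming the first offending feature and sample
check_value_range <- function(values, value_kind, where = "matrix") {
  bad <- switch(value_kind,
    fpkm   = which(values < 0, arr.ind = TRUE),
    beta   = which(values < 0 | values > 1, arr.ind = TRUE),
    matrix(integer(0), 0, 2))
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "%s: %s value %g out of range for feature '%s', sample '%s'",
      where, value_kind, values[i, j], rownames(values)[i], colnames(values)[j]),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples\n",
              x$value_kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Feature and sample identifiers of an omics matrix
#' @param x an \code{\link{omics_matrix}}.
#' @return character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

# subset an omics_matrix without re-validating ranges
om_subset <- function(x, features = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  structure(list(values = v, value_kind = x$value_kind), class = "omics_matrix")
}

as_omics <- function(x, value_kind) {
  if (inherits(x, "omics_matrix")) x else omics_matrix(x, value_kind)
}

#' EPIC-style probe manifest
#'
#' Per-probe genomic annotation used for probe filtering (sex chromosomes,
#' SNP-overlapping probes) and region-class summarization of differential
#' methylation.
#'
#' @param df data frame with columns \code{probe_id}, \code{chrom}
#'   (chr1..chr22, chrX, chrY), \code{position} (1-based), \code{gene}
#'   (empty string when intergenic), \code{region_class} (one of TSS,
#'   five_prime_UTR, first_exon, gene_body, three_prime_UTR, intergenic)
#'   and \code{snp_vaf} (population variant allele frequency in [0,1]).
#' @return validated data frame of class \code{probe_manifest}.
#' @export
probe_manifest <- function(df) {
  req <- c("probe_id", "chrom", "position", "gene", "region_class", "snp_vaf")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(df$probe_id)) {
    stop("duplicate probe ids in manifest: ",
         paste(head(unique(df$probe_id[duplicated(df$probe_id)]), 5), collapse = ", "),
         call. = FALSE)
  }
  chroms <- c(paste0("chr", 1:22), "chrX", "chrY")
  bad <- setdiff(unique(df$chrom), chroms)
  if (length(bad)) stop("manifest: unknown chromosome(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(unique(df$region_class), REGION_CLASSES)
  if (length(bad)) stop("manifest: unknown region class(es): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(!is.finite(df$snp_vaf)) || any(df$snp_vaf < 0 | df$snp_vaf > 1)) {
    i <- which(!is.finite(df$snp_vaf) | df$snp_vaf < 0 | df$snp_vaf > 1)[1]
    stop(sprintf("manifest: snp_vaf out of [0,1] for probe '%s'", df$probe_id[i]),
         call. = FALSE)
  }
  class(df) <- c("probe_manifest", "data.frame")
  df
}

#' Sample-level cohort metadata
#'
#' @param df data frame with columns \code{sample_id}, \code{timepoint}
#'   (diagnosis/relapse), \code{survival_time} (non-negative, unit
#'   consistent within the cohort), \code{event} (0 censored / 1 event);
#'   optional \code{tumor_fraction} in [0,1] (NA allowed),
#'   \code{histology} (common/LH/SCV/unknown) and \code{cn_altered}
#'   (logical, NA = unknown).  Extra columns are preserved untouched.
#' @return validated data frame of class \code{cohort_metadata}.
#' @export
cohort_metadata <- function(df) {
  req <- c("sample_id", "timepoint", "survival_time", "event")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  bad <- setdiff(unique(df$timepoint), c("diagnosis", "relapse"))
  if (length(bad)) stop("metadata: timepoint must be diagnosis/relapse, got: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.na(df$survival_time) & df$survival_time < 0)) {
    i <- which(df$survival_time < 0)[1]
    stop(sprintf("metadata: negative survival_time for sample '%s'", df$sample_id[i]),
         call. = FALSE)
  }
  if (any(!is.na(df$event) & !df$event %in% c(0, 1))) {
    i <- which(!df$event %in% c(0, 1))[1]
    stop(sprintf("metadata: event must be 0/1, got %s for sample '%s'",
                 df$event[i], df$sample_id[i]), call. = FALSE)
  }
  if (is.null(df$tumor_fraction)) df$tumor_fraction <- NA_real_
  tf <- df$tumor_fraction
  if (any(!is.na(tf) & (tf < 0 | tf > 1))) {
    i <- which(!is.na(tf) & (tf < 0 | tf > 1))[1]
    stop(sprintf("metadata: tumor_fraction out of [0,1] for sample '%s'",
                 df$sample_id[i]), call. = FALSE)
  }
  if (is.null(df$histology)) df$histology <- "unknown"
  bad <- setdiff(unique(df$histology), HISTOLOGIES)
  if (length(bad)) stop("metadata: unknown histology: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (is.null(df$cn_altered)) df$cn_altered <- NA
  df$cn_altered <- as.logical(df$cn_altered)
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' Gene-set library
#'
#' @param sets named list; each element a character vector of gene ids (or
#'   a list with elements \code{description} and \code{genes}).
#' @param descriptions optional character vector of set descriptions.
#' @return object of class \code{gene_set_library}: named list of
#'   \code{list(description, genes)} with deduplicated, non-empty gene
#'   vectors.
#' @export
gene_set_library <- function(sets, descriptions = NULL) {
  if (length(sets) && is.null(names(sets))) stop("sets must be named", call. = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate set names", call. = FALSE)
  out <- lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.list(s)) {
      desc <- if (!is.null(s$description)) s$description else ""
      genes <- s$genes
    } else {
      desc <- if (!is.null(descriptions)) descriptions[[i]] else ""
      genes <- s
    }
    genes <- unique(as.character(genes))
    if (length(genes) == 0) {
      stop(sprintf("gene set '%s' is empty", names(sets)[i]), call. = FALSE)
    }
    list(description = desc, genes = genes)
  })
  names(out) <- names(sets)
  structure(out, class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("gene_set_library: %d set(s)\n", length(x)))
  for (nm in head(names(x), 10)) {
    cat(sprintf("  %s (%d genes)\n", nm, length(x[[nm]]$genes)))
  }
  invisible(x)
}

set_genes <- function(library, name) {
  if (!name %in% names(library)) {
    stop(sprintf("unknown gene set '%s'", name), call. = FALSE)
  }
  library[[name]]$genes
}

#' Copy-number segment table
#'
#' Carrier type for upstream segmentation output (1-based inclusive
#' coordinates, as emitted by segmentation tools).
#'
#' @param df data frame with columns \code{sample_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{log2_ratio}, \code{call}
#'   (gain/loss/neutral).
#' @return validated data frame of class \code{segment_table}.
#' @export
segment_table <- function(df) {
  req <- c("sample_id", "chrom", "start", "end", "log2_ratio", "call")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("segment table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$start > df$end)) {
    i <- which(df$start > df$end)[1]
    stop(sprintf("segment table: start > end at record %d (%s:%d-%d)",
                 i, df$chrom[i], df$start[i], df$end[i]), call. = FALSE)
  }
  bad <- setdiff(unique(df$call), c("gain", "loss", "neutral"))
  if (length(bad)) stop("segment table: unknown call: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  class(df) <- c("segment_table", "data.frame")
  df
}

#' Somatic mutation table
#'
#' Carrier type for mutation calls (plotting/integration only).
#'
#' @param df data frame with columns \code{sample_id}, \code{gene},
#'   \code{protein_change}, \code{variant_class}, \code{vaf} in [0,1].
#' @return validated data frame of class \code{mutation_table}.
#' @export
mutation_table <- function(df) {
  req <- c("sample_id", "gene", "protein_change", "variant_class", "vaf")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("mutation table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.na(df$vaf) & (df$vaf < 0 | df$vaf > 1))) {
    i <- which(df$vaf < 0 | df$vaf > 1)[1]
    stop(sprintf("mutation table: vaf out of [0,1] at record %d", i), call. = FALSE)
  }
  class(df) <- c("mutation_table", "data.frame")
  df
}

# hypothesis-test result container used by all stats_core tests
test_result <- function(statistic, p_value, method_label, extras = list()) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p_value out of [0,1]", call. = FALSE)
  }
  structure(list(statistic = statistic, p_value = p_value,
                 method_label = method_label, extras = extras),
            class = "alcl_test")
}

#' @export
print.alcl_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g\n",
              x$method_label, x$statistic, x$p_value))
  if (length(x$extras)) {
    for (nm in names(x$extras)) {
      v <- x$extras[[nm]]
      if (is.numeric(v) && length(v) == 1) cat(sprintf("  %s = %.6g\n", nm, v))
    }
  }
  invisible(x)
}
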