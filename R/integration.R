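# Cross-platform integration: subgroup concordance, copy-number
# enrichment, over-representation analysis, and survival comparison of
# derived strata.

#' Cross-platform subgroup concordance
#'
#' Cross-tabulates the definite (non-unclassifiable) ALK-high/ALK-low
#' labels of samples assayed on both platforms, tests the association with
#' Fisher's exact test, and produces final per-sample labels: concordant
#' platform label when both agree, the single available platform's label
#' when only one platform covers the sample, unclassifiable when the
#' platforms disagree or either label is unclassifiable.
#'
#' @param labels_rna,labels_meth named factors/characters with values
#'   ALK_high / ALK_low / unclassifiable (expression- and
#'   methylation-based assignments).
#' @return list of class \code{concordance_report}: \code{n_shared}
#'   (definite labels on both platforms), \code{n_concordant},
#'   \code{fraction}, \code{fisher} (an \code{alcl_test}), \code{table},
#'   and \code{final_labels} over the union of samples.
#' @export
concordance <- function(labels_rna, labels_meth) {
  shared <- intersect(names(labels_rna), names(labels_meth))
  if (length(shared) == 0) stop("no shared samples across platforms", call. = FALSE)
  r <- as.character(labels_rna[shared]); m <- as.character(labels_meth[shared])
  definite <- r != "unclassifiable" & m != "unclassifiable"
  rd <- r[definite]; md <- m[definite]
  if (length(rd) == 0) stop("no shared samples with definite labels on both platforms",
                            call. = FALSE)
  tab <- table(factor(rd, c("ALK_high", "ALK_low")),
               factor(md, c("ALK_high", "ALK_low")))
  fis <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  n_conc <- sum(rd == md)

  all_ids <- union(names(labels_rna), names(labels_meth))
  final <- vapply(all_ids, function(id) {
    has_r <- id %in% names(labels_rna); has_m <- id %in% names(labels_meth)
    lr <- if (has_r) as.character(labels_rna[id]) else NA
    lm <- if (has_m) as.character(labels_meth[id]) else NA
    if (has_r && has_m) {
      if (lr == lm && lr != "unclassifiable") lr else "unclassifiable"
    } else if (has_r) lr else lm
  }, "")
  final <- factor(final, levels = c("ALK_high", "ALK_low", "unclassifiable"))
  names(final) <- all_ids
  log_stage("concordance", sprintf("%d/%d concordant (%.0f%%), Fisher p = %.3g",
                                   n_conc, length(rd), 100 * n_conc / length(rd),
                                   fis$p_value))
  structure(list(n_shared = length(rd), n_concordant = n_conc,
                 fraction = n_conc / length(rd), fisher = fis, table = tab,
                 final_labels = final, shared_samples = shared[definite]),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: %d/%d (%.1f%%), Fisher p = %.3g\n",
              x$n_concordant, x$n_shared, 100 * x$fraction, x$fisher$p_value))
  invisible(x)
}

#' Copy-number alteration enrichment by subgroup
#'
#' Fraction of CN-altered samples per final subgroup and a two-sided
#' Fisher's exact test of the altered/unaltered x ALK-high/ALK-low table.
#' Samples with unknown CN status are excluded from the table and counted
#' in the report.
#'
#' @param metadata a \code{\link{cohort_metadata}} with \code{cn_altered}.
#' @param labels named factor of final subgroup labels (ALK_high /
#'   ALK_low / unclassifiable).
#' @return list: \code{fractions} (named, per group), \code{counts}
#'   (altered/total per group), \code{fisher}, \code{n_unknown}.
#' @export
cn_enrichment <- function(metadata, labels) {
  ids <- intersect(metadata$sample_id, names(labels))
  lab <- as.character(labels[ids])
  cn <- metadata$cn_altered[match(ids, metadata$sample_id)]
  use <- lab %in% c("ALK_high", "ALK_low") & !is.na(cn)
  n_unknown <- sum(lab %in% c("ALK_high", "ALK_low") & is.na(cn))
  lab <- lab[use]; cn <- cn[use]
  for (g in c("ALK_high", "ALK_low")) {
    if (!any(lab == g)) {
      stop(sprintf("no samples with known CN status in group %s", g), call. = FALSE)
    }
  }
  a <- sum(lab == "ALK_high" & cn);  b <- sum(lab == "ALK_high" & !cn)
  cc <- sum(lab == "ALK_low" & cn); d <- sum(lab == "ALK_low" & !cn)
  fis <- fisher_exact_2x2(a, b, cc, d)
  fractions <- c(ALK_high = a / (a + b), ALK_low = cc / (cc + d))
  log_stage("cn_enrichment",
            sprintf("ALK_high %d/%d (%.1f%%) vs ALK_low %d/%d (%.2f%%), p = %.4g",
                    a, a + b, 100 * fractions[1], cc, cc + d, 100 * fractions[2],
                    fis$p_value))
  list(fractions = fractions,
       counts = data.frame(group = c("ALK_high", "ALK_low"),
                           altered = c(a, cc), total = c(a + b, cc + d)),
       fisher = fis, n_unknown = n_unknown)
}

#' Over-representation analysis of a gene list
#'
#' One-sided (enrichment) Fisher's exact test of the overlap between a
#' gene list and each set of a library, against a stated gene universe,
#' with Benjamini-Hochberg adjustment across sets.  Results are sorted by
#' -log10(p) descending.
#'
#' @param gene_list character vector, a subset of \code{universe}.
#' @param universe character vector of all candidate genes.
#' @param library a \code{\link{gene_set_library}}.
#' @return data frame: set, overlap, list_size, set_size, p, q,
#'   minus_log10_p, overlap_genes (semicolon-joined).
#' @export
over_representation <- function(gene_list, universe, library) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  gene_list <- unique(gene_list)
  out_of_universe <- setdiff(gene_list, universe)
  if (length(out_of_universe)) {
    stop("gene list not contained in universe: ",
         paste(head(out_of_universe, 5), collapse = ", "), call. = FALSE)
  }
  if (length(library) == 0) stop("empty gene-set library", call. = FALSE)
  rows <- lapply(names(library), function(nm) {
    set <- intersect(set_genes(library, nm), universe)
    ov <- intersect(gene_list, set)
    a <- length(ov)
    b <- length(gene_list) - a
    cc <- length(set) - a
    d <- length(universe) - a - b - cc
    fis <- fisher_exact_2x2(a, b, cc, d, alternative = "greater")
    data.frame(set = nm, overlap = a, list_size = length(gene_list),
               set_size = length(set), p = fis$p_value,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- benjamini_hochberg(out$p)
  out$minus_log10_p <- -log10(pmax(out$p, .Machine$double.xmin))
  out <- out[order(-out$minus_log10_p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("set", "overlap", "list_size", "set_size", "p", "q",
          "minus_log10_p", "overlap_genes")]
}

#' Survival comparison between two strata
#'
#' Kaplan-Meier curves per stratum and a log-rank test across them, over
#' the samples with complete survival data.
#'
#' @param metadata a \code{\link{cohort_metadata}} with survival_time and
#'   event.
#' @param strata named vector of stratum labels (exactly 2 distinct
#'   values among the usable samples).
#' @return list: \code{curves} (named list of
#'   \code{\link{km_estimate}} results), \code{logrank}
#'   (an \code{alcl_test}), \code{n} (per-stratum sample counts),
#'   \code{samples} (ids used).
#' @export
survival_by_stratum <- function(metadata, strata) {
  ids <- intersect(names(strata), metadata$sample_id)
  md <- metadata[match(ids, metadata$sample_id), ]
  ok <- !is.na(md$survival_time) & !is.na(md$event)
  ids <- ids[ok]; md <- md[ok, ]
  lab <- as.character(strata[ids])
  lv <- unique(lab)
  if (length(lv) != 2) {
    stop(sprintf("need exactly 2 strata with survival data, have %d", length(lv)),
         call. = FALSE)
  }
  curves <- lapply(lv, function(g) {
    sel <- lab == g
    if (!any(sel)) stop(sprintf("stratum '%s' empty after missing-data removal", g),
                        call. = FALSE)
    km_estimate(md$survival_time[sel], md$event[sel])
  })
  names(curves) <- lv
  lr <- logrank_test(md$survival_time, md$event, lab)
  log_stage("survival", sprintf("%s: n=%s, log-rank p = %.4g",
                                paste(lv, collapse = " vs "),
                                paste(table(lab)[lv], collapse = "/"), lr$p_value))
  list(curves = curves, logrank = lr,
       n = setNames(as.integer(table(lab)[lv]), lv), samples = ids)
}
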