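# Differential expression, relapse-signature derivation and median
# dichotomization of signature scores.

#' Convert FPKM to log2 expression
#'
#' log2(FPKM + 1); pseudocount 1 keeps zeros at zero.
#'
#' @param matrix an \code{\link{omics_matrix}} of kind \code{fpkm}.
#' @return an \code{omics_matrix} of kind \code{log2_expression}.
#' @export
as_log2_expression <- function(matrix) {
  if (matrix$value_kind == "log2_expression") return(matrix)
  if (matrix$value_kind != "fpkm") {
    stop("as_log2_expression expects an fpkm matrix", call. = FALSE)
  }
  omics_matrix(log2(matrix$values + 1), "log2_expression")
}

#' Differential expression between two groups
#'
#' Moderated-t comparison per gene (see \code{\link{moderated_t}}) with
#' Benjamini-Hochberg adjustment over all tested genes.  A gene is called
#' \code{up} when log2FC > \code{lfc_cut} and q < \code{q_cut}, \code{down}
#' symmetrically, otherwise \code{ns}.  FPKM input is log2(FPKM+1)
#' transformed first.
#'
#' @param matrix an \code{\link{omics_matrix}} (\code{fpkm} or
#'   \code{log2_expression}).
#' @param group_a,group_b disjoint sample-id vectors (>= 2 each); log2FC is
#'   group_a minus group_b.
#' @param lfc_cut log2 fold-change threshold (default 1.0).
#' @param q_cut adjusted-p threshold (default 0.05).
#' @return data frame of class \code{differential_result} with columns
#'   \code{feature_id}, \code{log2fc}, \code{statistic}, \code{p},
#'   \code{q}, \code{direction}; attributes \code{n_up}, \code{n_down}.
#' @export
differential_expression <- function(matrix, group_a, group_b,
                                    lfc_cut = 1.0, q_cut = 0.05) {
  work <- if (matrix$value_kind == "fpkm") as_log2_expression(matrix) else matrix
  mt <- moderated_t(work, group_a, group_b)
  q <- benjamini_hochberg(mt$p)
  direction <- rep("ns", nrow(mt))
  direction[mt$log2fc > lfc_cut & q < q_cut] <- "up"
  direction[mt$log2fc < -lfc_cut & q < q_cut] <- "down"
  out <- data.frame(feature_id = mt$feature_id, log2fc = mt$log2fc,
                    statistic = mt$t, p = mt$p, q = q, direction = direction,
                    stringsAsFactors = FALSE)
  attr(out, "n_up") <- sum(direction == "up")
  attr(out, "n_down") <- sum(direction == "down")
  class(out) <- c("differential_result", "data.frame")
  log_stage("de", sprintf("%d genes tested: %d up, %d down (|log2FC|>%g, q<%g)",
                          nrow(out), attr(out, "n_up"), attr(out, "n_down"),
                          lfc_cut, q_cut))
  out
}

#' Derive a relapse expression signature
#'
#' Compares relapse against diagnosis samples and keeps genes
#' significantly up-regulated in relapse under the conjunctive rule:
#' raw p < \code{p_cut}, log2FC > \code{lfc_cut} and BH-adjusted
#' q < \code{q_cut}.  An empty signature is returned with a warning, not
#' an error.
#'
#' @param matrix expression \code{\link{omics_matrix}}.
#' @param relapse_ids,diagnosis_ids disjoint sample-id vectors (>= 2 each).
#' @param p_cut raw p threshold (default 0.01).
#' @param lfc_cut log2 fold-change threshold (default 1).
#' @param q_cut adjusted-p threshold (default 0.25).
#' @return a one-set \code{\link{gene_set_library}} named
#'   \code{relapse_signature} (empty genes allowed only as a zero-set
#'   library); the full differential table is attached as attribute
#'   \code{"differential"}.
#' @export
derive_relapse_signature <- function(matrix, relapse_ids, diagnosis_ids,
                                     p_cut = 0.01, lfc_cut = 1, q_cut = 0.25) {
  de <- differential_expression(matrix, relapse_ids, diagnosis_ids,
                                lfc_cut = lfc_cut, q_cut = q_cut)
  keep <- de$p < p_cut & de$log2fc > lfc_cut & de$q < q_cut
  genes <- de$feature_id[keep]
  desc <- sprintf("up in relapse vs diagnosis (p<%g, log2FC>%g, q<%g)",
                  p_cut, lfc_cut, q_cut)
  log_stage("relapse_signature", sprintf("%d gene(s) selected", length(genes)))
  if (length(genes) == 0) {
    warning("relapse signature is empty under the given thresholds")
    lib <- gene_set_library(setNames(list(), character(0)))
  } else {
    lib <- gene_set_library(list(relapse_signature = genes),
                            descriptions = desc)
  }
  attr(lib, "differential") <- de
  lib
}

#' Median dichotomization of signature scores
#'
#' Splits samples into HIGH/LOW at the median score of a reference subset
#' (the diagnosis samples in the relapse-score analysis).  Samples exactly
#' at the median are LOW.
#'
#' @param scores named numeric vector of per-sample scores.
#' @param reference_ids non-empty subset of the scored samples over which
#'   the median is computed.
#' @return data frame of class \code{signature_scorecard}: sample_id,
#'   score, stratum (HIGH/LOW), reference_median.
#' @export
dichotomize_by_median <- function(scores, reference_ids) {
  if (length(reference_ids) == 0) stop("empty reference set", call. = FALSE)
  missing <- setdiff(reference_ids, names(scores))
  if (length(missing)) {
    stop("reference ids not scored: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  ref_med <- median(scores[reference_ids])
  out <- data.frame(sample_id = names(scores), score = unname(scores),
                    stratum = ifelse(scores > ref_med, "HIGH", "LOW"),
                    reference_median = ref_med, stringsAsFactors = FALSE)
  class(out) <- c("signature_scorecard", "data.frame")
  out
}
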