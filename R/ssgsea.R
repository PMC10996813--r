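# Single-sample gene-set enrichment: per-sample scores from ranked
# expression via a weighted/unweighted ECDF difference.

#' Single-sample GSEA score
#'
#' For each sample, genes are ranked by expression (average ranks for
#' ties, highest expression = largest rank) and walked in decreasing
#' order; the score is the sum over the ranked list of the difference
#' between the within-set weighted ECDF (weights = rank^alpha) and the
#' out-of-set unweighted ECDF.  Scores are rank-based, hence invariant to
#' any monotone transform of a sample's expression values.
#'
#' @param matrix expression \code{\link{omics_matrix}} (any expression
#'   kind; only ranks are used).
#' @param gene_set character vector of gene ids; its intersection with the
#'   matrix features must be non-empty and a proper subset of them.
#' @param alpha rank-weighting exponent (default 0.75, the canonical
#'   single-sample GSEA choice).
#' @param normalize if TRUE, min-max normalize the scores across samples.
#' @return named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(matrix, gene_set, alpha = 0.75, normalize = FALSE) {
  m <- matrix$values
  genes <- rownames(m)
  set <- intersect(unique(gene_set), genes)
  if (length(set) == 0) stop("gene set does not intersect matrix features", call. = FALSE)
  if (length(set) == length(genes)) {
    stop("gene set covers every feature; enrichment undefined", call. = FALSE)
  }
  in_set <- genes %in% set
  n <- length(genes)
  scores <- vapply(seq_len(ncol(m)), function(j) {
    x <- m[, j]
    rk <- rank(x, ties.method = "average")      # largest expression -> rank n
    ord <- order(-x, genes)                     # walk top-down, ties by gene id
    w <- ifelse(in_set[ord], rk[ord]^alpha, 0)
    hit <- cumsum(w) / sum(w)
    miss <- cumsum(!in_set[ord]) / (n - length(set))
    sum(hit - miss)
  }, 0)
  names(scores) <- colnames(m)
  if (normalize) {
    rng <- range(scores)
    if (diff(rng) > 0) scores <- (scores - rng[1]) / diff(rng)
    else scores[] <- 0
  }
  scores
}

#' Gene-program scores per sample
#'
#' Scores each named program of a gene-set library by single-sample GSEA
#' and summarizes with the mean across the requested programs (used e.g.
#' as a summary immune score across immune programs).
#'
#' @param matrix expression \code{\link{omics_matrix}}.
#' @param library a \code{\link{gene_set_library}}.
#' @param programs set names to score (duplicates ignored).
#' @param alpha rank-weighting exponent passed to \code{\link{ssgsea_score}}.
#' @return list: \code{scores} (samples x programs matrix) and
#'   \code{summary} (per-sample mean across programs).
#' @export
program_score <- function(matrix, library, programs, alpha = 0.75) {
  programs <- unique(programs)
  unknown <- setdiff(programs, names(library))
  if (length(unknown)) {
    stop("unknown program(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sc <- do.call(cbind, lapply(programs, function(p) {
    g <- set_genes(library, p)
    if (length(intersect(g, feature_ids(matrix))) == 0) {
      stop(sprintf("program '%s' has no genes in the matrix", p), call. = FALSE)
    }
    ssgsea_score(matrix, g, alpha = alpha)
  }))
  dimnames(sc) <- list(sample_ids(matrix), programs)
  list(scores = sc, summary = rowMeans(sc))
}
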