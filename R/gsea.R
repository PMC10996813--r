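# Two-group gene-set enrichment: signal-to-noise ranking, weighted
# running-sum enrichment scores, phenotype-label permutation null,
# normalized scores and the canonical positive/negative pooled FDR.

# ES of one set on a ranked score vector (names = genes, sorted desc)
gsea_es <- function(scores_sorted, in_set, weight = 1) {
  n <- length(scores_sorted)
  n_set <- sum(in_set)
  if (n_set == 0 || n_set == n) {
    stop("gene set must be a non-empty proper subset of ranked genes", call. = FALSE)
  }
  w <- ifelse(in_set, abs(scores_sorted)^weight, 0)
  sw <- sum(w)
  if (sw == 0) w[in_set] <- 1 / n_set else w <- w / sw
  run <- cumsum(w - ifelse(in_set, 0, 1 / (n - n_set)))
  i <- which.max(abs(run))
  list(es = run[i], peak = i, running = run)
}

rank_scores <- function(matrix, group_a, group_b) {
  s <- signal_to_noise(matrix, group_a, group_b)
  s[order(-s, names(s))]
}

#' Gene-set enrichment analysis (two groups, phenotype permutation)
#'
#' Genes are ranked by signal-to-noise between the groups; each set's
#' enrichment score (ES) is the maximal deviation of the weighted running
#' sum (weight = |score|).  Significance comes from permuting the group
#' labels: NES = ES divided by the mean |null ES| of the same sign, the
#' nominal p is the same-sign permutation tail (floored at 1/(n_perm+1),
#' the resolution of the null), and the FDR q pools observed and null NES across
#' sets within each sign, per the canonical procedure.
#'
#' @param matrix expression \code{\link{omics_matrix}} (\code{fpkm} input
#'   is log2(FPKM+1) transformed before scoring).
#' @param group_a,group_b disjoint sample-id vectors, each >= 3 (phenotype
#'   permutation needs enough labels; gene-set permutation is not
#'   implemented).
#' @param library a \code{\link{gene_set_library}}.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed (results are reproducible given the seed).
#' @return data frame: set, size, es, nes, nominal_p, fdr_q,
#'   leading_edge (semicolon-joined gene ids), sorted by nominal_p.
#' @export
gsea <- function(matrix, group_a, group_b, library, n_perm = 1000, seed = 1) {
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop("phenotype permutation needs >= 3 samples per group", call. = FALSE)
  }
  if (length(library) == 0) stop("empty gene-set library", call. = FALSE)
  work <- if (matrix$value_kind == "fpkm") as_log2_expression(matrix) else matrix
  obs_scores <- rank_scores(work, group_a, group_b)
  genes_sorted <- names(obs_scores)
  set_members <- lapply(library, function(s) genes_sorted %in% s$genes)
  obs <- lapply(set_members, function(m) gsea_es(obs_scores, m))
  obs_es <- vapply(obs, `[[`, 0, "es")

  all_ids <- c(group_a, group_b)
  na <- length(group_a)
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      pa <- sample(all_ids, na)
      ps <- rank_scores(work, pa, setdiff(all_ids, pa))
      pm <- lapply(library, function(s) names(ps) %in% s$genes)
      vapply(seq_along(library), function(i) gsea_es(ps, pm[[i]])$es, 0)
    }, numeric(length(library)))
  })
  null_es <- matrix(null_es, nrow = length(library))

  nes <- nominal_p <- numeric(length(library))
  null_nes <- matrix(NA_real_, nrow = length(library), ncol = n_perm)
  for (i in seq_along(library)) {
    nulls <- null_es[i, ]
    same <- nulls[sign(nulls) == sign(obs_es[i]) | nulls == 0]
    denom <- mean(abs(same))
    if (!is.finite(denom) || denom == 0) denom <- mean(abs(nulls))
    nes[i] <- obs_es[i] / denom
    # same-sign permutation tail, floored so p never drops below the
    # resolution of the permutation null
    tail_frac <- if (length(same)) mean(abs(same) >= abs(obs_es[i])) else 0
    nominal_p[i] <- max(tail_frac, 1 / (n_perm + 1))
    pos <- nulls > 0; neg <- nulls < 0
    mp <- mean(nulls[pos]); mn <- mean(abs(nulls[neg]))
    nn <- nulls
    nn[pos] <- nulls[pos] / mp
    nn[neg] <- nulls[neg] / mn
    null_nes[i, ] <- nn
  }
  # pooled positive/negative FDR
  fdr_q <- vapply(seq_along(library), function(i) {
    s <- sign(nes[i]); if (s == 0) return(1)
    pool <- null_nes[sign(null_nes) == s]
    obs_pool <- nes[sign(nes) == s]
    num <- mean(abs(pool) >= abs(nes[i]))
    den <- mean(abs(obs_pool) >= abs(nes[i]))
    if (den == 0) return(1)
    min(1, num / den)
  }, 0)
  leading <- vapply(seq_along(library), function(i) {
    o <- obs[[i]]
    idx <- if (o$es >= 0) seq_len(o$peak) else o$peak:length(genes_sorted)
    paste(genes_sorted[idx][set_members[[i]][idx]], collapse = ";")
  }, "")
  out <- data.frame(set = names(library),
                    size = vapply(set_members, sum, 0L),
                    es = obs_es, nes = nes, nominal_p = nominal_p,
                    fdr_q = fdr_q, leading_edge = leading,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$nominal_p, -abs(out$nes)), , drop = FALSE]
}
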