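# Subgroup discovery: variable-feature ranking (MAD / variance / dip),
# correlation-distance hierarchical clustering under two linkages, a
# bootstrap feature-stability sweep, consensus across the six
# statistic x linkage combinations, and marker-based ALK-high/ALK-low
# labeling.

CLUSTER_STATISTICS <- c("mad", "variance", "dip")
CLUSTER_LINKAGES <- c("complete", "average")

# put expression on log2(FPKM + 1); methylation is clustered on M-values
prepare_for_clustering <- function(matrix) {
  switch(matrix$value_kind,
    fpkm = omics_matrix(log2(matrix$values + 1), "log2_expression"),
    beta = beta_to_m(matrix),
    matrix)
}

#' Rank features by across-sample variability
#'
#' Orders features by median absolute deviation, variance, or the dip
#' statistic computed across samples, descending, with deterministic
#' lexicographic tie-break on feature id.  Dip-ranked lists favor features
#' whose values split into two clumps (bimodal across the cohort), which
#' is what separates molecular subgroups.
#'
#' @param matrix an \code{\link{omics_matrix}} of kind
#'   \code{log2_expression} or \code{m_value} (use
#'   \code{\link{as_log2_expression}} / \code{\link{beta_to_m}} first).
#' @param statistic \code{"mad"}, \code{"variance"} or \code{"dip"}.
#' @return character vector of feature ids, most variable first, with the
#'   statistic values as a \code{"stat"} attribute.
#' @export
rank_variable_features <- function(matrix, statistic = c("mad", "variance", "dip")) {
  statistic <- match.arg(statistic)
  if (!matrix$value_kind %in% c("log2_expression", "m_value")) {
    stop("rank_variable_features expects log2_expression or m_value input; got ",
         matrix$value_kind, call. = FALSE)
  }
  m <- matrix$values
  if (ncol(m) < 4) stop("feature ranking needs >= 4 samples", call. = FALSE)
  stat <- switch(statistic,
    mad = apply(m, 1, mad),
    variance = apply(m, 1, var),
    dip = dip_rows(m))
  ord <- order(-stat, rownames(m))
  out <- rownames(m)[ord]
  attr(out, "stat") <- stat[ord]
  out
}

#' Hierarchical clustering cut over selected features
#'
#' Agglomerative clustering of samples on the distance
#' 1 - Pearson correlation computed over the selected features, cut into
#' \code{k} groups.  A sample with a constant profile over the selected
#' features has undefined correlation and raises an error naming it.
#'
#' @param matrix an \code{\link{omics_matrix}} (log scale).
#' @param features character vector (>= 2) of feature ids to cluster on;
#'   duplicates allowed (bootstrap resamples reuse rows).
#' @param linkage \code{"complete"} or \code{"average"}.
#' @param k number of groups (default 2).
#' @return integer vector of cluster labels (1..k) named by sample id.
#' @export
hierarchical_cut <- function(matrix, features, linkage = c("complete", "average"),
                             k = 2) {
  linkage <- match.arg(linkage)
  if (length(features) < 2) stop("need >= 2 features to cluster", call. = FALSE)
  m <- matrix$values[features, , drop = FALSE]
  if (ncol(m) < 3) stop("need >= 3 samples to cluster", call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop("constant profile (correlation undefined) for sample(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  d <- as.dist(1 - cor(m))
  hc <- hclust(d, method = linkage)
  cutree(hc, k = k)
}

# clustering cut under integer feature weights: identical to expanding
# each feature row w times and running hierarchical_cut (weighted Pearson
# correlation computed via crossprod)
weighted_cor_cut <- function(X, w, linkage, k = 2) {
  W <- sum(w)
  mu <- colSums(X * w) / W
  C <- crossprod(X, X * w) - W * tcrossprod(mu)
  v <- diag(C)
  if (any(v <= 0)) {
    stop("constant profile (correlation undefined) for sample(s): ",
         paste(colnames(X)[v <= 0], collapse = ", "), call. = FALSE)
  }
  r <- C / sqrt(tcrossprod(v))
  hc <- hclust(as.dist(1 - r), method = linkage)
  cutree(hc, k = k)
}

#' Bootstrap support for a two-group partition
#'
#' Resamples the selected features (rows) with replacement \code{B} times,
#' re-clusters, and returns the fraction of replicates whose k = 2
#' bipartition is identical (as an unordered set partition) to the
#' full-data bipartition.  Replicates that degenerate (a sample constant
#' across the resampled features) count as non-matching and are logged.
#'
#' @inheritParams hierarchical_cut
#' @param B number of bootstrap replicates (>= 1).
#' @param seed integer seed; the caller's RNG state is restored afterwards.
#' @return fraction in [0, 1]; attribute \code{"n_degenerate"} counts
#'   degenerate replicates.
#' @export
bootstrap_partition_probability <- function(matrix, features,
                                            linkage = c("complete", "average"),
                                            k = 2, B = 100, seed = 1) {
  linkage <- match.arg(linkage)
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (length(features) < 10) stop("bootstrap needs >= 10 features", call. = FALSE)
  full <- hierarchical_cut(matrix, features, linkage, k = k)
  nf <- length(features)
  X <- matrix$values[features, , drop = FALSE]
  res <- with_seed(seed, {
    hits <- 0L; degen <- 0L
    for (b in seq_len(B)) {
      w <- tabulate(sample.int(nf, nf, replace = TRUE), nbins = nf)
      labs <- tryCatch(weighted_cor_cut(X, w, linkage, k = k),
                       error = function(e) NULL)
      if (is.null(labs)) degen <- degen + 1L
      else if (same_bipartition(labs, full)) hits <- hits + 1L
    }
    c(hits, degen)
  })
  if (res[2] > 0) {
    log_stage("bootstrap", sprintf("%d/%d degenerate replicate(s) counted as non-matching",
                                   res[2], B))
  }
  structure(res[1] / B, n_degenerate = res[2])
}

#' Feature-count stability sweep
#'
#' Computes the bootstrap partition probability while steadily increasing
#' the number of top-ranked features, and selects the smallest count whose
#' support reaches \code{support_threshold} and whose assignment agrees
#' (>= 90\% after optimal label alignment) with the top-1000-feature
#' reference assignment.  If no count qualifies, the count with maximal
#' support is returned flagged unstable.
#'
#' @param matrix an \code{\link{omics_matrix}} (log scale).
#' @param statistic,linkage one statistic and one linkage (see
#'   \code{\link{rank_variable_features}}, \code{\link{hierarchical_cut}}).
#' @param feature_counts increasing vector of feature counts to try;
#'   counts exceeding the number of available features are dropped.
#' @param B bootstrap replicates per count.
#' @param seed integer seed.
#' @param support_threshold minimum bootstrap probability (default 0.70).
#' @return list: \code{selected_count}, \code{assignment} (labels at the
#'   selected count), \code{stable} flag, \code{curve} (data frame of
#'   count, bootstrap probability, reference agreement) and
#'   \code{reference} (top-1000 assignment).
#' @export
stability_sweep <- function(matrix, statistic, linkage,
                            feature_counts = c(250, 500, 1000, 2000, 4000),
                            B = 100, seed = 1, support_threshold = 0.70) {
  ranked <- rank_variable_features(matrix, statistic)
  feature_counts <- sort(unique(feature_counts))
  feature_counts <- feature_counts[feature_counts <= length(ranked)]
  if (length(feature_counts) == 0) stop("no usable feature counts", call. = FALSE)
  if (is.unsorted(feature_counts, strictly = TRUE)) {
    stop("feature_counts must be strictly increasing", call. = FALSE)
  }
  ref <- hierarchical_cut(matrix, ranked[seq_len(min(1000, length(ranked)))], linkage)
  bp <- agree <- numeric(length(feature_counts))
  assigns <- vector("list", length(feature_counts))
  for (i in seq_along(feature_counts)) {
    feats <- ranked[seq_len(feature_counts[i])]
    assigns[[i]] <- hierarchical_cut(matrix, feats, linkage)
    bp[i] <- bootstrap_partition_probability(matrix, feats, linkage, B = B,
                                             seed = seed + i)
    agree[i] <- partition_agreement(assigns[[i]], ref)
  }
  curve <- data.frame(count = feature_counts, bootstrap_probability = bp,
                      reference_agreement = agree)
  ok <- which(bp >= support_threshold & agree >= 0.90)
  if (length(ok)) {
    sel <- ok[1]; stable <- TRUE
  } else {
    sel <- which.max(bp); stable <- FALSE
  }
  log_stage("stability_sweep",
            sprintf("%s/%s: selected %d features (support %.2f, stable=%s)",
                    statistic, linkage, feature_counts[sel], bp[sel], stable))
  list(selected_count = feature_counts[sel], assignment = assigns[[sel]],
       stable = stable, curve = curve, reference = ref)
}

#' Consensus subgroup assignment across clustering methods
#'
#' Aligns the two-group labels of each method to the first method by the
#' maximal-agreement swap, then assigns each sample the strict-majority
#' label across methods; samples without a strict majority are
#' unclassifiable.
#'
#' @param assignments named list of integer label vectors (1/2), all over
#'   the same samples (>= 2 methods).
#' @return factor per sample with levels \code{group1}, \code{group2},
#'   \code{unclassifiable}; attribute \code{"votes"} holds the aligned
#'   vote matrix.
#' @export
consensus_assignment <- function(assignments) {
  if (length(assignments) < 2) stop("need >= 2 method assignments", call. = FALSE)
  ref <- assignments[[1]]
  samples <- sort(names(ref))
  for (a in assignments) {
    if (!identical(sort(names(a)), samples)) {
      stop("method assignments cover different sample sets", call. = FALSE)
    }
  }
  aligned <- lapply(assignments, function(a) {
    a <- a[names(ref)]
    if (mean(a == ref) >= mean((3 - a) == ref)) a else 3 - a
  })
  votes <- do.call(rbind, aligned)
  n_methods <- nrow(votes)
  lab <- apply(votes, 2, function(v) {
    n1 <- sum(v == 1)
    if (n1 > n_methods / 2) "group1"
    else if ((n_methods - n1) > n_methods / 2) "group2"
    else "unclassifiable"
  })
  out <- factor(lab, levels = c("group1", "group2", "unclassifiable"))
  names(out) <- names(ref)
  n_un <- sum(out == "unclassifiable")
  log_stage("consensus", sprintf("%d method(s), %d sample(s), %d unclassifiable",
                                 n_methods, length(out), n_un))
  attr(out, "votes") <- votes
  out
}

#' Label consensus groups by a marker gene
#'
#' The consensus cluster with the higher median marker expression becomes
#' \code{ALK_high}, the other \code{ALK_low}; unclassifiable samples keep
#' their flag.  Ties in the medians raise an error demanding an explicit
#' override (no silent tie-break).  Also reports a two-sided Wilcoxon
#' rank-sum test of the marker difference between the groups.
#'
#' @param consensus factor from \code{\link{consensus_assignment}}.
#' @param matrix an \code{\link{omics_matrix}} containing the marker.
#' @param marker_gene feature id of the marker (default \code{"ALK"}).
#' @param high_group optional override: \code{"group1"} or \code{"group2"}
#'   to force which consensus group is ALK_high (used when medians tie).
#' @return list: \code{labels} (factor ALK_high/ALK_low/unclassifiable per
#'   sample), \code{medians}, \code{test} (Wilcoxon).
#' @export
label_by_marker <- function(consensus, matrix, marker_gene = "ALK",
                            high_group = NULL) {
  if (!marker_gene %in% feature_ids(matrix)) {
    stop(sprintf("marker gene '%s' absent from matrix", marker_gene), call. = FALSE)
  }
  expr <- matrix$values[marker_gene, names(consensus)]
  g1 <- names(consensus)[consensus == "group1"]
  g2 <- names(consensus)[consensus == "group2"]
  if (length(g1) == 0 || length(g2) == 0) {
    stop("both consensus groups must be non-empty", call. = FALSE)
  }
  med <- c(group1 = median(expr[g1]), group2 = median(expr[g2]))
  if (is.null(high_group)) {
    if (med["group1"] == med["group2"]) {
      stop("marker medians tie between groups; pass `high_group` explicitly",
           call. = FALSE)
    }
    high_group <- if (med["group1"] > med["group2"]) "group1" else "group2"
  }
  lab <- ifelse(consensus == "unclassifiable", "unclassifiable",
                ifelse(consensus == high_group, "ALK_high", "ALK_low"))
  labels <- factor(lab, levels = c("ALK_high", "ALK_low", "unclassifiable"))
  names(labels) <- names(consensus)
  test <- wilcoxon_rank_sum(expr[g1], expr[g2])
  list(labels = labels, medians = med, test = test)
}

#' Full subtype clustering pipeline
#'
#' Runs the stability sweep for every statistic x linkage combination
#' (3 x 2 by default), takes the consensus assignment, and labels the
#' groups by the marker gene.  FPKM input is log2(FPKM+1)-transformed and
#' beta input converted to M-values before clustering.
#'
#' @param matrix an \code{\link{omics_matrix}} (fpkm, log2_expression,
#'   beta or m_value).
#' @param marker_gene marker used to orient the groups, or \code{NULL} to
#'   skip marker labeling (e.g. for methylation matrices; use
#'   \code{\link{label_by_marker}} afterwards with expression data, or
#'   label by cross-platform transfer).
#' @param statistics,linkages method grid (defaults: mad/variance/dip x
#'   complete/average).
#' @param feature_counts,B,seed,support_threshold see
#'   \code{\link{stability_sweep}}.
#' @return list of class \code{cluster_outcome}: per-method sweeps,
#'   \code{consensus}, \code{marker} (or NULL), \code{labels} (marker
#'   labels when available, else consensus labels).
#' @export
cluster_subtypes <- function(matrix, marker_gene = "ALK",
                             statistics = CLUSTER_STATISTICS,
                             linkages = CLUSTER_LINKAGES,
                             feature_counts = c(250, 500, 1000, 2000, 4000),
                             B = 100, seed = 1, support_threshold = 0.70) {
  work <- prepare_for_clustering(matrix)
  log_stage("cluster", sprintf("%d features x %d samples (%s), B=%d, seed=%d",
                               nrow(work$values), ncol(work$values),
                               work$value_kind, B, seed))
  sweeps <- list()
  i <- 0
  for (st in statistics) for (lk in linkages) {
    i <- i + 1
    sweeps[[paste(st, lk, sep = "_")]] <-
      stability_sweep(work, st, lk, feature_counts = feature_counts, B = B,
                      seed = seed + 1000 * i, support_threshold = support_threshold)
  }
  consensus <- consensus_assignment(lapply(sweeps, `[[`, "assignment"))
  marker <- NULL
  labels <- consensus
  if (!is.null(marker_gene)) {
    marker <- label_by_marker(consensus, work, marker_gene)
    labels <- marker$labels
  }
  structure(list(sweeps = sweeps, consensus = consensus, marker = marker,
                 labels = labels),
            class = "cluster_outcome")
}

#' @export
print.cluster_outcome <- function(x, ...) {
  cat("cluster_outcome:\n")
  for (nm in names(x$sweeps)) {
    s <- x$sweeps[[nm]]
    cat(sprintf("  %-18s count=%4d support=%.2f %s\n", nm, s$selected_count,
                s$curve$bootstrap_probability[s$curve$count == s$selected_count],
                if (s$stable) "" else "(unstable)"))
  }
  cat("  consensus:", paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                            collapse = " "), "\n")
  invisible(x)
}
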