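# EPIC-style methylation processing: beta/M conversion, probe and sample
# filters, probe-level differential methylation with region-class
# summarization, beta-distribution profiling and probe-to-marker
# correlation screening.

#' Convert beta values to M-values
#'
#' \eqn{M = \log_2(\beta / (1 - \beta))} after clamping beta to
#' \eqn{[\epsilon, 1-\epsilon]}; the variance-stabilized scale used for
#' testing and clustering.
#'
#' @param matrix an \code{\link{omics_matrix}} of kind \code{beta}.
#' @param epsilon clamp margin (default 1e-6).
#' @return an \code{omics_matrix} of kind \code{m_value}.
#' @export
beta_to_m <- function(matrix, epsilon = 1e-6) {
  if (matrix$value_kind != "beta") stop("beta_to_m expects a beta matrix", call. = FALSE)
  b <- pmin(pmax(matrix$values, epsilon), 1 - epsilon)
  omics_matrix(log2(b / (1 - b)), "m_value")
}

#' Convert M-values back to beta values
#' @param matrix an \code{\link{omics_matrix}} of kind \code{m_value}.
#' @return an \code{omics_matrix} of kind \code{beta}.
#' @export
m_to_beta <- function(matrix) {
  if (matrix$value_kind != "m_value") stop("m_to_beta expects an m_value matrix",
                                           call. = FALSE)
  omics_matrix(2^matrix$values / (1 + 2^matrix$values), "beta")
}

#' Filter probes on sex chromosomes and SNP overlap
#'
#' Removes probes on chrX/chrY and probes whose overlapping SNP population
#' allele frequency exceeds \code{snp_vaf_cut} (strictly; a probe at
#' exactly the cut is retained).  The two filters commute; the report
#' counts each removal reason disjointly (chrX/Y first).
#'
#' @param matrix beta or M-value \code{\link{omics_matrix}}.
#' @param manifest a \code{\link{probe_manifest}} covering every probe in
#'   the matrix.
#' @param snp_vaf_cut SNP allele-frequency cutoff (default 0.01).
#' @return list: \code{matrix} (filtered), \code{report} (counts and the
#'   removed probe ids per reason).
#' @export
filter_probes <- function(matrix, manifest, snp_vaf_cut = 0.01) {
  probes <- feature_ids(matrix)
  missing <- setdiff(probes, manifest$probe_id)
  if (length(missing)) {
    stop("probe(s) missing from manifest: ",
         paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10),
         call. = FALSE)
  }
  mf <- manifest[match(probes, manifest$probe_id), ]
  is_xy <- mf$chrom %in% c("chrX", "chrY")
  is_snp <- !is_xy & mf$snp_vaf > snp_vaf_cut
  keep <- !is_xy & !is_snp
  report <- list(n_input = length(probes),
                 chrXY = sum(is_xy), snp = sum(is_snp),
                 n_retained = sum(keep),
                 removed_chrXY = probes[is_xy], removed_snp = probes[is_snp])
  log_stage("filter_probes",
            sprintf("%d probes: removed %d chrX/Y, %d SNP (VAF>%g); %d retained",
                    report$n_input, report$chrXY, report$snp, snp_vaf_cut,
                    report$n_retained))
  list(matrix = om_subset(matrix, features = probes[keep]), report = report)
}

#' Filter samples by tumor purity
#'
#' Removes samples whose tumor fraction is below \code{min_fraction}
#' (strictly; a sample at exactly the threshold is retained).  Samples
#' with missing tumor fraction are retained with a warning.
#'
#' @param matrix an \code{\link{omics_matrix}}.
#' @param metadata a \code{\link{cohort_metadata}} covering the samples.
#' @param min_fraction minimum tumor fraction (default 0.40).
#' @return list: \code{matrix} (filtered), \code{report} (removed and
#'   missing-fraction sample ids).
#' @export
filter_samples_by_purity <- function(matrix, metadata, min_fraction = 0.40) {
  ids <- sample_ids(matrix)
  tf <- metadata$tumor_fraction[match(ids, metadata$sample_id)]
  low <- !is.na(tf) & tf < min_fraction
  miss <- is.na(tf)
  if (any(miss)) {
    warning("tumor fraction missing for sample(s) ",
            paste(ids[miss], collapse = ", "), "; retained")
  }
  report <- list(removed = ids[low], missing_fraction = ids[miss],
                 n_input = length(ids), n_retained = sum(!low))
  log_stage("filter_purity", sprintf("%d samples: removed %d with fraction < %g",
                                     length(ids), sum(low), min_fraction))
  list(matrix = om_subset(matrix, samples = ids[!low]), report = report)
}

# vectorized per-probe two-sided Wilcoxon rank-sum p-values; exact via a
# cached null distribution per tie pattern when n <= 20, else normal
# approximation with tie correction
wilcox_p_rows <- function(m, group_a, group_b) {
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  sub <- m[, c(group_a, group_b), drop = FALSE]
  exact <- n <= 20
  cache <- new.env(parent = emptyenv())
  apply(sub, 1, function(x) {
    r <- rank(x, ties.method = "average")
    w <- sum(r[seq_len(na)])
    ew <- na * (n + 1) / 2
    if (exact) {
      r2 <- round(2 * r)
      key <- paste(sort(r2), collapse = ",")
      null <- get0(key, envir = cache)
      if (is.null(null)) {
        null <- wilcox_exact_null(r2, na)
        assign(key, null, envir = cache)
      }
      sum(null$prob[abs(null$support - 2 * ew) >= abs(2 * w - 2 * ew) - 1e-9])
    } else {
      tt <- table(r)
      v <- na * nb / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
      if (v <= 0) return(1)
      z <- if (w == ew) 0 else (w - ew - sign(w - ew) * 0.5) / sqrt(v)
      min(1, 2 * pnorm(-abs(z)))
    }
  })
}

#' Differential methylation between two groups
#'
#' Per-probe two-sided Wilcoxon rank-sum test on M-values with
#' Benjamini-Hochberg adjustment across all tested probes; effect sizes
#' are reported as delta-beta (mean beta of group_a minus group_b, the
#' interpretable scale).  A probe is \code{hyper} (in group_a) when
#' q < \code{q_cut} and delta-beta > 0, \code{hypo} symmetrically,
#' otherwise \code{ns}.
#'
#' @param m_matrix M-value \code{\link{omics_matrix}} (tested scale).
#' @param beta_matrix matching beta \code{\link{omics_matrix}} (same
#'   probes; effect-size scale).
#' @param group_a,group_b disjoint sample-id vectors, each >= 3.
#' @param q_cut adjusted-p threshold (default 0.05).
#' @param manifest optional \code{\link{probe_manifest}} to annotate
#'   \code{region_class}.
#' @return data frame of class \code{dmp_result}: probe_id, delta_beta,
#'   p, q, direction, and region_class when a manifest is given.
#' @export
differential_methylation <- function(m_matrix, beta_matrix, group_a, group_b,
                                     q_cut = 0.05, manifest = NULL) {
  if (!identical(feature_ids(m_matrix), feature_ids(beta_matrix))) {
    stop("M-value and beta matrices carry different probe sets", call. = FALSE)
  }
  check_groups(m_matrix$values, group_a, group_b, min_size = 3)
  p <- wilcox_p_rows(m_matrix$values, group_a, group_b)
  q <- benjamini_hochberg(p)
  db <- rowMeans(beta_matrix$values[, group_a, drop = FALSE]) -
        rowMeans(beta_matrix$values[, group_b, drop = FALSE])
  direction <- rep("ns", length(p))
  direction[q < q_cut & db > 0] <- "hyper"
  direction[q < q_cut & db < 0] <- "hypo"
  out <- data.frame(probe_id = feature_ids(m_matrix), delta_beta = db,
                    p = p, q = q, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(manifest)) {
    out$region_class <- manifest$region_class[match(out$probe_id, manifest$probe_id)]
  }
  class(out) <- c("dmp_result", "data.frame")
  log_stage("dmp", sprintf("%d probes tested: %d hyper, %d hypo (q<%g)",
                           nrow(out), sum(direction == "hyper"),
                           sum(direction == "hypo"), q_cut))
  out
}

#' Summarize differentially methylated probes by genomic region class
#'
#' Counts hyper-/hypomethylated calls per region class (TSS, gene body,
#' ...).  The counts conserve the total number of non-ns calls.
#'
#' @param dmp a \code{dmp_result} from
#'   \code{\link{differential_methylation}}.
#' @param manifest a \code{\link{probe_manifest}} annotating every called
#'   probe.
#' @return data frame: region_class, n_hyper, n_hypo.
#' @export
summarize_regions <- function(dmp, manifest) {
  rc <- manifest$region_class[match(dmp$probe_id, manifest$probe_id)]
  if (any(is.na(rc))) {
    stop("probe(s) missing from manifest: ",
         paste(head(dmp$probe_id[is.na(rc)], 5), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(rc), REGION_CLASSES)
  if (length(bad)) stop("unknown region class: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  out <- data.frame(region_class = REGION_CLASSES,
                    n_hyper = vapply(REGION_CLASSES, function(r)
                      sum(dmp$direction == "hyper" & rc == r), 0L),
                    n_hypo = vapply(REGION_CLASSES, function(r)
                      sum(dmp$direction == "hypo" & rc == r), 0L),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Beta-distribution profile per group
#'
#' Pools the beta values of each group's samples and reports a 50-bin
#' histogram over [0,1], the fraction of values at intermediate
#' methylation (0.33, 0.66), and the dip statistic of the pooled values as
#' a bimodality index (a bimodal hypo/hyper profile has a large dip; a
#' mid-centered moderate profile a small one).  For speed the dip is
#' computed on at most \code{max_dip_n} evenly-spaced order statistics of
#' the pooled values, which perturbs the statistic by at most
#' \eqn{1/(2 \cdot max\_dip\_n)}.
#'
#' @param beta_matrix beta \code{\link{omics_matrix}}.
#' @param group_labels named vector/factor of group labels per sample
#'   (every matrix sample must be labeled; each group non-empty).
#' @param bins histogram bin count (default 50).
#' @param mid_range interval of "intermediate" methylation (default
#'   c(0.33, 0.66), open).
#' @param max_dip_n subsample cap for the dip computation (default 2000).
#' @return named list per group: \code{histogram} (counts), \code{breaks},
#'   \code{fraction_mid}, \code{dip}, \code{n_values}.
#' @export
beta_profile <- function(beta_matrix, group_labels, bins = 50,
                         mid_range = c(0.33, 0.66), max_dip_n = 2000) {
  ids <- sample_ids(beta_matrix)
  miss <- setdiff(ids, names(group_labels))
  if (length(miss)) stop("unlabeled sample(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  groups <- unique(as.character(group_labels[ids]))
  breaks <- seq(0, 1, length.out = bins + 1)
  out <- lapply(groups, function(g) {
    sel <- ids[as.character(group_labels[ids]) == g]
    if (length(sel) == 0) stop(sprintf("empty group '%s'", g), call. = FALSE)
    v <- as.numeric(beta_matrix$values[, sel])
    h <- tabulate(pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1),
                       bins), nbins = bins)
    vv <- sort(v)
    if (length(vv) > max_dip_n) {
      vv <- vv[unique(round(seq(1, length(vv), length.out = max_dip_n)))]
    }
    list(histogram = h, breaks = breaks,
         fraction_mid = mean(v > mid_range[1] & v < mid_range[2]),
         dip = dip_statistic(vv), n_values = length(v))
  })
  names(out) <- groups
  out
}

#' Correlate methylation probes with marker-gene expression
#'
#' Spearman rank correlation of every probe (M-values by default; the
#' conversion is monotone so beta gives identical ranks) against the
#' marker gene's expression across the shared samples.  Probes with
#' |rho| >= \code{rho_cut} are selected and split by correlation sign into
#' deduplicated gene lists (via the manifest) for downstream
#' over-representation analysis.  Constant probes have undefined rank
#' correlation: they get NA rho, are never selected, and are counted in
#' the report.
#'
#' @param m_matrix methylation \code{\link{omics_matrix}} (m_value or
#'   beta).
#' @param expression_matrix expression \code{\link{omics_matrix}}
#'   containing the marker gene.
#' @param manifest a \code{\link{probe_manifest}} (maps probes to genes).
#' @param marker_gene marker feature id (default \code{"ALK"}).
#' @param rho_cut absolute-correlation cutoff (default 0.75).
#' @return list: \code{records} (probe_id, rho, selected, sign, gene),
#'   \code{positive_genes}, \code{negative_genes}, \code{n_shared},
#'   \code{n_constant}.
#' @export
correlate_with_expression <- function(m_matrix, expression_matrix, manifest,
                                      marker_gene = "ALK", rho_cut = 0.75) {
  if (!marker_gene %in% feature_ids(expression_matrix)) {
    stop(sprintf("marker gene '%s' absent from expression matrix", marker_gene),
         call. = FALSE)
  }
  shared <- intersect(sample_ids(m_matrix), sample_ids(expression_matrix))
  if (length(shared) < 5) {
    stop(sprintf("need >= 5 shared samples, have %d", length(shared)), call. = FALSE)
  }
  mv <- m_matrix$values[, shared, drop = FALSE]
  marker <- expression_matrix$values[marker_gene, shared]
  ry <- rank(marker, ties.method = "average")
  dy <- ry - mean(ry); sy <- sqrt(sum(dy^2))
  if (sy == 0) stop("marker expression is constant across shared samples", call. = FALSE)
  rx <- t(apply(mv, 1, rank, ties.method = "average"))
  dx <- rx - rowMeans(rx)
  sx <- sqrt(rowSums(dx^2))
  rho <- as.numeric(dx %*% dy) / (sx * sy)
  rho[sx == 0] <- NA_real_
  rho <- pmin(pmax(rho, -1), 1)
  selected <- !is.na(rho) & abs(rho) >= rho_cut
  gene <- manifest$gene[match(feature_ids(m_matrix), manifest$probe_id)]
  records <- data.frame(probe_id = feature_ids(m_matrix), rho = rho,
                        selected = selected,
                        sign = ifelse(is.na(rho), NA_character_,
                                      ifelse(rho >= 0, "positive", "negative")),
                        gene = ifelse(is.na(gene), "", gene),
                        row.names = NULL, stringsAsFactors = FALSE)
  pos <- unique(records$gene[records$selected & records$sign == "positive" &
                               nzchar(records$gene)])
  neg <- unique(records$gene[records$selected & records$sign == "negative" &
                               nzchar(records$gene)])
  log_stage("correlate",
            sprintf("%d probes vs %s over %d samples: %d selected (|rho|>=%g)",
                    nrow(records), marker_gene, length(shared), sum(selected),
                    rho_cut))
  list(records = records, positive_genes = pos, negative_genes = neg,
       n_shared = length(shared), n_constant = sum(is.na(rho)))
}
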