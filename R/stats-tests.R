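# Rank and contingency tests plus multiplicity adjustment; self-contained
# so their conventions (two-sided rules, tie handling, continuity
# correction) are explicit and oracle-checkable.

#' Spearman rank correlation
#'
#' Pearson correlation of average-rank vectors (midranks for ties).
#' A constant vector has undefined rank correlation and raises an error
#' rather than silently returning 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("spearman_rho needs length >= 3", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("spearman_rho: non-finite values", call. = FALSE)
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) {
    stop("spearman_rho: correlation undefined for a constant vector", call. = FALSE)
  }
  r <- sum(dx * dy) / (sx * sy)
  max(-1, min(1, r))
}

# exact null distribution of the doubled rank sum of group x, over all
# C(n, nx) assignments, by the shift algorithm on doubled midranks.
# Returns list(support, prob): doubled-rank-sum values and probabilities.
wilcox_exact_null <- function(ranks2, nx) {
  n <- length(ranks2)
  maxs <- sum(sort(ranks2, decreasing = TRUE)[seq_len(nx)])
  # counts[k+1, s+1] = number of size-k subsets with doubled sum s
  counts <- matrix(0, nrow = nx + 1, ncol = maxs + 1)
  counts[1, 1] <- 1
  for (r in ranks2) {
    kmax <- nx
    for (k in kmax:1) {
      nz <- which(counts[k, ] > 0)
      if (length(nz)) {
        tgt <- nz + r
        keep <- tgt <= maxs + 1
        counts[k + 1, tgt[keep]] <- counts[k + 1, tgt[keep]] + counts[k, nz[keep]]
      }
    }
  }
  tot <- counts[nx + 1, ]
  support <- which(tot > 0) - 1
  list(support = support, prob = tot[support + 1] / sum(tot))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of a location difference between two independent groups.
#' The exact mode enumerates the permutation distribution of the rank sum
#' (midranks for ties, so it remains exact under ties); the normal
#' approximation applies a continuity correction and the usual tie
#' correction to the variance.  Two-sided p in exact mode is
#' \eqn{P(|W - E W| \ge |w - E W|)} under the permutation null.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param mode \code{"auto"} (exact when \eqn{n_x + n_y \le 20}, else
#'   normal approximation), \code{"exact"}, or \code{"normal_approx"}.
#' @return an \code{alcl_test} with statistic = rank sum of \code{x}.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) {
    stop("wilcoxon_rank_sum: both groups must be non-empty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (mode == "auto") mode <- if (n <= 20) "exact" else "normal_approx"
  if (mode == "exact" && n > 20) {
    stop("exact mode requires n_x + n_y <= 20; use normal_approx", call. = FALSE)
  }
  r <- rank(c(x, y), ties.method = "average")
  w <- sum(r[seq_len(nx)])
  ew <- nx * (n + 1) / 2
  if (mode == "exact") {
    ranks2 <- round(2 * r)  # doubled midranks are integers
    null <- wilcox_exact_null(ranks2, nx)
    dev <- abs(null$support - 2 * ew)
    p <- sum(null$prob[dev >= abs(2 * w - 2 * ew) - 1e-9])
  } else {
    tie_tab <- table(r)
    tie_corr <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    v <- nx * ny / 12 * ((n + 1) - tie_corr)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (w - ew - sign(w - ew) * 0.5) / sqrt(v)
      if (w == ew) z <- 0
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  test_result(w, p, sprintf("Wilcoxon rank-sum (%s)", mode),
              extras = list(n_x = nx, n_y = ny, expected = ew))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the probability-mass method: the sum of hypergeometric
#' probabilities of all tables with the same margins whose probability does
#' not exceed that of the observed table (within a relative tolerance of
#' 1e-7, so knife-edge ties are included).  One-sided alternatives sum the
#' corresponding tail.  The odds ratio reported is the sample odds ratio
#' \eqn{ad/bc} (infinite when \eqn{bc = 0}).
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   \code{[[a, b], [c, d]]}.
#' @param alternative \code{"two.sided"} (default), \code{"greater"}
#'   (enrichment of cell a), or \code{"less"}.
#' @return an \code{alcl_test} with \code{extras$odds_ratio}.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("fisher_exact_2x2: cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("fisher_exact_2x2: empty table", call. = FALSE)
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  xs <- lo:hi
  logp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k)
  pr <- exp(logp)
  p_obs <- pr[xs == a]
  p <- switch(alternative,
    two.sided = sum(pr[pr <= p_obs * (1 + 1e-7)]),
    greater   = sum(pr[xs >= a]),
    less      = sum(pr[xs <= a]))
  p <- min(1, p)
  or <- if (b * c == 0) { if (a * d == 0) NaN else Inf } else (a * d) / (b * c)
  test_result(a, p, sprintf("Fisher exact (%s)", alternative),
              extras = list(odds_ratio = or, margins = c(m1, m2, k)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j},
#' capped at 1.  Preserves the ranking of the input p-values.
#'
#' @param p numeric vector of p-values in [0, 1] (NA passed through).
#' @return adjusted q-values, same order as input.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("benjamini_hochberg: p-values must lie in [0,1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(q)
  o <- order(p[ok])
  ranked <- p[ok][o] * m / seq_len(m)
  ranked <- rev(cummin(rev(ranked)))
  ranked <- pmin(ranked, 1)
  q[ok][o] <- ranked
  q
}
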