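# Empirical-Bayes moderated t-statistics and the GSEA signal-to-noise
# ratio, the two per-feature effect scores the expression module ranks by.

# invert trigamma by Newton iteration (monotone decreasing on (0, Inf))
trigamma_inverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

# method-of-moments fit of the scaled inverse-chi-square prior for
# per-feature variances: match mean/variance of z = log s^2 to the
# digamma/trigamma expressions.  Returns list(d0, s02); d0 = Inf when the
# observed log-variances are under-dispersed relative to chi-square noise.
fit_variance_prior <- function(s2, df) {
  pos <- s2 > 0
  if (sum(pos) < 2) return(list(d0 = Inf, s02 = max(mean(s2), 1e-12)))
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated two-group t-statistics
#'
#' Per-feature two-group comparison on a log2-scale matrix with
#' empirical-Bayes variance moderation: per-feature pooled variances
#' \eqn{s_g^2} (df \eqn{d_g = n_a + n_b - 2}) are shrunk toward a prior
#' \eqn{(d_0, s_0^2)} estimated by method of moments on \eqn{\log s_g^2},
#' giving posterior variances
#' \eqn{\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)} and
#' t-statistics on \eqn{d_0 + d_g} degrees of freedom.  Zero-variance
#' features are handled through the prior (no division by zero).  When the
#' log-variances are under-dispersed the prior inversion fails and the fit
#' falls back to \eqn{d_0 = \infty} (all features share \eqn{s_0^2}).
#'
#' @param matrix an \code{\link{omics_matrix}} on a log2 scale
#'   (\code{log2_expression} or \code{m_value}), or a plain numeric matrix.
#' @param group_a,group_b disjoint character vectors of sample ids, each of
#'   size >= 2.  The reported log2 fold change is group_a minus group_b.
#' @return data frame with columns \code{feature_id}, \code{log2fc},
#'   \code{t}, \code{p}, \code{df_total}; attributes \code{d0} and
#'   \code{s02} carry the fitted prior.
#' @export
moderated_t <- function(matrix, group_a, group_b) {
  m <- if (inherits(matrix, "omics_matrix")) {
    if (!matrix$value_kind %in% c("log2_expression", "m_value")) {
      stop("moderated_t expects a log-scale matrix (log2_expression or m_value)",
           call. = FALSE)
    }
    matrix$values
  } else matrix
  check_groups(m, group_a, group_b, min_size = 2)
  na <- length(group_a); nb <- length(group_b)
  ma <- rowMeans(m[, group_a, drop = FALSE])
  mb <- rowMeans(m[, group_b, drop = FALSE])
  ssa <- rowSums((m[, group_a, drop = FALSE] - ma)^2)
  ssb <- rowSums((m[, group_b, drop = FALSE] - mb)^2)
  df <- na + nb - 2
  s2 <- (ssa + ssb) / df
  prior <- fit_variance_prior(s2, df)
  stilde2 <- if (is.infinite(prior$d0)) rep(prior$s02, length(s2))
             else (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df)
  lfc <- ma - mb
  tmod <- lfc / sqrt(stilde2 * (1 / na + 1 / nb))
  df_total <- prior$d0 + df
  p <- 2 * pt(-abs(tmod), df = df_total)
  out <- data.frame(feature_id = rownames(m), log2fc = lfc, t = tmod, p = p,
                    df_total = df_total, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "d0") <- prior$d0
  attr(out, "s02") <- prior$s02
  out
}

#' Signal-to-noise ratio per feature
#'
#' The GSEA ranking metric \eqn{(\mu_a - \mu_b)/(\sigma_a + \sigma_b)},
#' with each group's standard deviation floored at
#' \eqn{\max(0.2 |\mu|, 0.2)} so that low-variance features cannot produce
#' unbounded scores (the convention of the canonical GSEA implementation).
#'
#' @inheritParams moderated_t
#' @return named numeric vector of per-feature scores.
#' @export
signal_to_noise <- function(matrix, group_a, group_b) {
  m <- if (inherits(matrix, "omics_matrix")) matrix$values else matrix
  check_groups(m, group_a, group_b, min_size = 2)
  ma <- rowMeans(m[, group_a, drop = FALSE])
  mb <- rowMeans(m[, group_b, drop = FALSE])
  sa <- apply(m[, group_a, drop = FALSE], 1, sd)
  sb <- apply(m[, group_b, drop = FALSE], 1, sd)
  sa <- pmax(sa, 0.2 * abs(ma), 0.2)
  sb <- pmax(sb, 0.2 * abs(mb), 0.2)
  setNames((ma - mb) / (sa + sb), rownames(m))
}

check_groups <- function(m, group_a, group_b, min_size = 2) {
  if (length(intersect(group_a, group_b))) {
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing)) {
    stop("samples not in matrix: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(group_a) < min_size || length(group_b) < min_size) {
    stop(sprintf("each group needs >= %d samples", min_size), call. = FALSE)
  }
  invisible(TRUE)
}
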