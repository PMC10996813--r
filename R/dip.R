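#' Hartigan-Hartigan dip statistic
#'
#' Departure of a sample from unimodality: the minimum over all unimodal
#' CDFs U (convex left of the mode, concave right of it, with a jump
#' allowed only at the mode) of the sup-norm distance between U and the
#' empirical CDF.  Used both to rank features whose across-sample
#' distribution is bimodal (e.g. methylation probes split between two
#' subgroups) and to profile pooled beta-value distributions.
#'
#' Computed by bisection on the band half-width with an exact feasibility
#' check: a unimodal CDF fits inside the band \eqn{[F_n - D, F_n + D]} iff
#' for some mode placement the minimal convex envelope through the band's
#' left flank stays below the maximal concave envelope through its right
#' flank.  For a sample of n distinct values the statistic lies in
#' \eqn{[1/(2n), 0.25]}; it is invariant to affine transforms of the data.
#'
#' @param x numeric vector, all finite, length at least 4.
#' @return the dip statistic, a single number.
#' @examples
#' dip_statistic(c(1, 2, 3, 4))            # 0.125, the n = 4 lower bound
#' dip_statistic(rep(c(0, 1), each = 10))  # 0.25, two balanced point masses
#' @export
dip_statistic <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  if (any(!is.finite(x))) stop("dip_statistic: non-finite values in input", call. = FALSE)
  if (length(x) < 4) {
    stop(sprintf("dip_statistic needs at least 4 observations, got %d", length(x)),
         call. = FALSE)
  }
  cpp_dip(as.numeric(x))
}

# row-wise dip for feature ranking (each row needs >= 4 finite values)
dip_rows <- function(m) {
  if (ncol(m) < 4) stop("dip ranking needs at least 4 samples", call. = FALSE)
  if (any(!is.finite(m))) stop("dip ranking: non-finite values in matrix", call. = FALSE)
  setNames(cpp_dip_rows(m), rownames(m))
}
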