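# Product-limit survival estimation and the two-group log-rank test.

#' Kaplan-Meier estimator
#'
#' Product-limit estimate of the survival function.  With only censored
#' observations the estimate is constant 1 (no event times listed).
#'
#' @param times non-negative follow-up times.
#' @param events 0 (censored) / 1 (event) per observation.
#' @return object of class \code{survival_curve}: list with increasing
#'   event \code{times}, non-increasing \code{survival} step values, the
#'   number \code{at_risk} just before each event time, and \code{n_events}
#'   at each.
#' @export
km_estimate <- function(times, events) {
  if (length(times) != length(events)) stop("times/events length mismatch", call. = FALSE)
  if (any(times < 0)) stop("km_estimate: negative time", call. = FALSE)
  if (any(!events %in% c(0, 1))) stop("km_estimate: events must be 0/1", call. = FALSE)
  ut <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(0); risk <- integer(0); nev <- integer(0)
  for (t in ut) {
    r <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / r)
    surv <- c(surv, s); risk <- c(risk, r); nev <- c(nev, d)
  }
  structure(list(times = ut, survival = surv, at_risk = risk, n_events = nev,
                 n = length(times)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event time(s)\n", x$n, length(x$times)))
  if (length(x$times)) {
    print(data.frame(time = x$times, at_risk = x$at_risk, events = x$n_events,
                     survival = round(x$survival, 4)))
  }
  invisible(x)
}

#' Two-group log-rank test
#'
#' Chi-square statistic \eqn{(O - E)^2 / V} on 1 df comparing the observed
#' event count in one group with its hypergeometric expectation across all
#' distinct event times.  When no variance accumulates (e.g. everything
#' censored) the test is degenerate: statistic 0, p = 1, with a warning.
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 per observation.
#' @param groups group labels (exactly 2 distinct values, both non-empty).
#' @return an \code{alcl_test} with \code{extras}: observed and expected
#'   events per group.
#' @export
logrank_test <- function(times, events, groups) {
  if (length(unique(groups)) != 2) {
    stop("logrank_test requires exactly 2 non-empty groups", call. = FALSE)
  }
  if (any(times < 0)) stop("logrank_test: negative time", call. = FALSE)
  g <- as.integer(factor(groups))
  ut <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in ut) {
    at <- times >= t
    r <- sum(at); r1 <- sum(at & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    o1 <- o1 + d1
    e1 <- e1 + r1 * d / r
    if (r > 1) v <- v + d * (r1 / r) * (1 - r1 / r) * (r - d) / (r - 1)
  }
  if (v <= 0) {
    warning("log-rank test degenerate: no variance (all censored or one group at risk)")
    return(test_result(0, 1, "log-rank",
                       extras = list(observed = o1, expected = e1, variance = v)))
  }
  chi <- (o1 - e1)^2 / v
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  test_result(chi, p, "log-rank",
              extras = list(observed = o1, expected = e1, variance = v))
}
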