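# internal helpers shared across modules

# one line per pipeline stage; silent unless options(alclomics.verbose = TRUE)
log_stage <- function(stage, ...) {
  if (isTRUE(getOption("alclomics.verbose", FALSE))) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }
  invisible(NULL)
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples,
#' used to compare recovered subgroups with planted truth.  1 means
#' identical partitions, 0 is the expectation under independent labelings.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a number \eqn{\le 1}.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length", call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}

# best two-group label alignment: fraction of samples agreeing after the
# optimal 1<->2 swap (labels are 1/2 integers over identical sample names)
partition_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  max(mean(a == b), mean(a != b))
}

same_bipartition <- function(a, b) partition_agreement(a, b) == 1
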