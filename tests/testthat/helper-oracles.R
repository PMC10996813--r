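# Independent oracles and small fixture builders used across the suite.

# quick omics_matrix from a numeric matrix
om <- function(m, kind = "log2_expression",
               features = sprintf("f%03d", seq_len(nrow(m))),
               samples = sprintf("s%02d", seq_len(ncol(m)))) {
  dimnames(m) <- list(features, samples)
  omics_matrix(m, kind)
}

# ---- dip statistic: LP minimization of the band half-width over
# piecewise-linear unimodal CDFs with the mode on a fine grid (quadprog) --
dip_lp_oracle <- function(x, grid = 24) {
  x <- sort(x)
  n <- length(x)
  v <- unique(x)
  m <- length(v)
  if (m == 1) return(0)
  cum <- vapply(v, function(z) mean(x <= z), 0)
  prev <- vapply(v, function(z) mean(x < z), 0)
  solve_candidate <- function(px, plo, phi, part, junction = NULL) {
    P <- length(px); nv <- P + 1
    rows <- list(); rhs <- c()
    add <- function(a, b0) { rows[[length(rows) + 1]] <<- a; rhs <<- c(rhs, b0) }
    for (i in seq_len(P)) {
      if (is.finite(plo[i])) { a <- numeric(nv); a[i] <- 1; a[nv] <- 1; add(a, plo[i]) }
      if (is.finite(phi[i])) { a <- numeric(nv); a[i] <- -1; a[nv] <- 1; add(a, -phi[i]) }
      a <- numeric(nv); a[i] <- 1; add(a, 0)
      a <- numeric(nv); a[i] <- -1; add(a, -1)
    }
    for (pt in c(1, 2)) {
      idx <- which(part == pt)
      if (length(idx) >= 3) {
        for (t in seq_len(length(idx) - 2)) {
          i1 <- idx[t]; i2 <- idx[t + 1]; i3 <- idx[t + 2]
          a <- numeric(nv); s <- if (pt == 1) 1 else -1
          a[i3] <- s * (px[i2] - px[i1])
          a[i2] <- s * (-(px[i2] - px[i1]) - (px[i3] - px[i2]))
          a[i1] <- s * (px[i3] - px[i2])
          add(a, 0)
        }
      }
    }
    cidx <- which(part == 1); kidx <- which(part == 2)
    if (length(cidx) >= 2) { a <- numeric(nv); a[cidx[2]] <- 1; a[cidx[1]] <- -1; add(a, 0) }
    if (length(kidx) >= 2) {
      a <- numeric(nv); a[kidx[length(kidx)]] <- 1; a[kidx[length(kidx) - 1]] <- -1
      add(a, 0)
    }
    if (!is.null(junction)) { a <- numeric(nv); a[junction[2]] <- 1; a[junction[1]] <- -1; add(a, 0) }
    a <- numeric(nv); a[nv] <- 1; add(a, 0)
    Amat <- t(do.call(rbind, rows))
    ans <- tryCatch(quadprog::solve.QP(diag(1e-9, nv), c(rep(0, P), -1), Amat, rhs),
                    error = function(e) NULL)
    if (is.null(ans)) return(Inf)
    ans$solution[nv]
  }
  best <- Inf
  best <- min(best, solve_candidate(v, cum, prev, rep(2, m)))
  best <- min(best, solve_candidate(v, cum, prev, rep(1, m)))
  for (j in seq_len(m)) {
    px <- c(v[seq_len(j - 1)], v[j], v[j], v[seq_len(m - j) + j])
    plo <- c(cum[seq_len(j - 1)], -Inf, cum[j], cum[seq_len(m - j) + j])
    phi <- c(prev[seq_len(j - 1)], prev[j], Inf, prev[seq_len(m - j) + j])
    part <- c(rep(1, j), rep(2, m - j + 1))
    best <- min(best, solve_candidate(px, plo, phi, part, junction = c(j, j + 1)))
  }
  for (k in seq_len(m - 1)) {
    for (g in seq_len(grid)) {
      mm <- v[k] + (v[k + 1] - v[k]) * g / (grid + 1)
      px <- c(v[seq_len(k)], mm, mm, v[seq_len(m - k) + k])
      plo <- c(cum[seq_len(k)], -Inf, -Inf, cum[seq_len(m - k) + k])
      phi <- c(prev[seq_len(k)], Inf, Inf, prev[seq_len(m - k) + k])
      part <- c(rep(1, k + 1), rep(2, m - k + 1))
      best <- min(best, solve_candidate(px, plo, phi, part, junction = c(k + 1, k + 2)))
    }
  }
  best
}

# ---- brute-force agglomeration: rescan all pairwise cluster distances
# at every step ----
brute_agglomerate <- function(d, linkage, k = 2) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  while (length(clusters) > k) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dd <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        dij <- if (linkage == "complete") max(dd) else mean(dd)
        if (dij < best) { best <- dij; bi <- i; bj <- j }
      }
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  lab <- integer(nrow(d))
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# ---- exact Wilcoxon two-sided p by full enumeration over C(n, nx)
# group assignments ----
wilcox_enum_p <- function(x, y) {
  r <- rank(c(x, y), ties.method = "average")
  nx <- length(x); N <- length(r)
  combs <- utils::combn(N, nx)
  Ws <- colSums(matrix(r[combs], nrow = nx))
  E <- nx * (N + 1) / 2
  w <- sum(r[seq_len(nx)])
  mean(abs(Ws - E) >= abs(w - E) - 1e-9)
}

# ---- Fisher two-sided p by direct hypergeometric summation over all
# admissible tables ----
fisher_enum_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  xs <- max(0, k - m2):min(k, m1)
  pr <- choose(m1, xs) * choose(m2, k - xs) / choose(m1 + m2, k)
  p_obs <- pr[xs == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# ---- literal running-sum ssGSEA for one sample ----
ssgsea_hand <- function(expr, genes, set, alpha = 0.75) {
  rk <- rank(expr, ties.method = "average")
  ord <- order(-expr, genes)
  in_set <- genes %in% set
  n <- length(genes)
  hit <- miss <- 0; total_w <- sum(rk[ord][in_set[ord]]^alpha)
  es <- 0
  for (i in seq_len(n)) {
    g <- ord[i]
    if (in_set[g]) hit <- hit + rk[g]^alpha / total_w
    else miss <- miss + 1 / (n - sum(in_set))
    es <- es + (hit - miss)
  }
  unname(es)
}

# planted two-group expression matrix: n1+n2 samples, n_inf informative
# features shifted by `shift` in group 1, rest noise
planted_matrix <- function(n1 = 8, n2 = 8, n_feat = 300, n_inf = 60,
                           shift = 2, sd = 0.6, seed = 1, mixed = TRUE) {
  set.seed(seed)
  mu <- rnorm(n_feat, 5, 1)   # shared per-feature baseline
  m <- mu + matrix(rnorm(n_feat * (n1 + n2), 0, sd), n_feat, n1 + n2)
  # mixed: heterogeneous planted effects (both directions, varying
  # magnitude), so the informative block alone carries a group-specific
  # pattern; otherwise a uniform upward shift for direction-sensitive tests
  shifts <- if (mixed) shift * runif(n_inf, 0.5, 1.5) * rep_len(c(1, -1), n_inf)
            else rep(shift, n_inf)
  m[seq_len(n_inf), seq_len(n1)] <- m[seq_len(n_inf), seq_len(n1)] + shifts
  om(m)
}
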