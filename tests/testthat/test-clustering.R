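# Feature ranking, hierarchical cut vs brute-force oracle, bootstrap
# support, stability sweep, consensus, marker labeling.

test_that("constant features rank last; dip promotes bimodal over variance-matched unimodal", {
  set.seed(31)
  X <- matrix(rnorm(20 * 12, 5), 20, 12)
  X[7, ] <- 3                              # constant
  bi <- rep(c(0, 4), each = 6) + rnorm(12, sd = 0.1)
  X[3, ] <- 5 + (bi - mean(bi))            # strongly bimodal
  X[9, ] <- 5 + rnorm(12, sd = sd(bi))     # unimodal, variance-matched
  m <- om(X)
  for (st in c("mad", "variance", "dip")) {
    expect_identical(rank_variable_features(m, st)[20], "f007")
  }
  rk <- rank_variable_features(m, "dip")
  expect_lt(which(rk == "f003"), which(rk == "f009"))
  # mad/variance rankings equal the direct per-feature oracles
  fid <- rownames(m$values)
  expect_identical(as.character(rank_variable_features(m, "mad")),
                   fid[order(-apply(m$values, 1, mad), fid)])
  expect_identical(as.character(rank_variable_features(m, "variance")),
                   fid[order(-apply(m$values, 1, var), fid)])
})

test_that("hierarchical_cut splits duplicated profiles perfectly and is order invariant", {
  set.seed(7)
  p1 <- rnorm(30); p2 <- rnorm(30)
  X <- cbind(a1 = p1 + rnorm(30, sd = 1e-3), a2 = p1 + rnorm(30, sd = 1e-3),
             b1 = p2 + rnorm(30, sd = 1e-3), b2 = p2 + rnorm(30, sd = 1e-3))
  rownames(X) <- sprintf("f%03d", 1:30)
  m <- omics_matrix(X, "log2_expression")
  for (lk in c("complete", "average")) {
    lab <- hierarchical_cut(m, rownames(X), lk)
    expect_equal(lab[["a1"]], lab[["a2"]])
    expect_equal(lab[["b1"]], lab[["b2"]])
    expect_true(lab[["a1"]] != lab[["b1"]])
  }
  perm <- sample(colnames(X))
  m2 <- omics_matrix(X[, perm], "log2_expression")
  l1 <- hierarchical_cut(m, rownames(X), "average")
  l2 <- hierarchical_cut(m2, rownames(X), "average")
  expect_true(same_partition <- alclomics:::same_bipartition(l1[names(l2)], l2))
})

test_that("hierarchical_cut agrees with a brute-force rescanning agglomeration oracle", {
  set.seed(19)
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 6, 5), 40, 6,
                dimnames = list(sprintf("f%03d", 1:40), sprintf("s%02d", 1:6)))
    m <- omics_matrix(X, "log2_expression")
    d <- as.dist(1 - cor(X))
    for (lk in c("complete", "average")) {
      for (k in 2:4) {
        mine <- hierarchical_cut(m, rownames(X), lk, k = k)
        oracle <- brute_agglomerate(d, lk, k = k)
        expect_equal(adjusted_rand_index(mine, oracle), 1,
                     label = sprintf("linkage=%s k=%d rep=%d", lk, k, rep))
      }
    }
  }
  Xc <- matrix(rnorm(30), 10, 3); Xc[, 2] <- 1
  dimnames(Xc) <- list(sprintf("f%03d", 1:10), c("s1", "sconst", "s3"))
  expect_error(hierarchical_cut(omics_matrix(Xc, "log2_expression"),
                                rownames(Xc), "complete"),
               "sconst")
})

test_that("bootstrap support is high for planted structure, low for noise, reproducible", {
  m <- planted_matrix(n1 = 8, n2 = 8, n_feat = 400, n_inf = 120, shift = 3,
                      sd = 0.5, seed = 42)
  feats <- rank_variable_features(m, "variance")[1:200]
  bp <- bootstrap_partition_probability(m, feats, "complete", B = 200, seed = 9)
  expect_gte(bp, 0.95)

  set.seed(55)
  noise <- om(matrix(rnorm(400 * 16, 5), 400, 16))
  nf <- rank_variable_features(noise, "variance")[1:200]
  bpn <- bootstrap_partition_probability(noise, nf, "complete", B = 200, seed = 9)
  expect_lt(bpn, 0.70)

  b1 <- bootstrap_partition_probability(m, feats, "average", B = 1, seed = 3)
  expect_true(as.numeric(b1) %in% c(0, 1))
  expect_identical(as.numeric(b1),
                   as.numeric(bootstrap_partition_probability(m, feats, "average",
                                                              B = 1, seed = 3)))
})

test_that("bootstrap support is monotone in planted effect size", {
  sup <- vapply(c(0.5, 1.5, 3), function(shift) {
    m <- planted_matrix(n1 = 8, n2 = 8, n_feat = 300, n_inf = 80, shift = shift,
                        sd = 0.8, seed = 101)
    feats <- rank_variable_features(m, "variance")[1:150]
    as.numeric(bootstrap_partition_probability(m, feats, "complete", B = 100, seed = 5))
  }, 0)
  expect_true(all(diff(sup) >= 0))
})

test_that("stability sweep selects the smallest supported count on strong structure", {
  m <- planted_matrix(n1 = 8, n2 = 8, n_feat = 600, n_inf = 150, shift = 3,
                      sd = 0.5, seed = 8)
  sw <- stability_sweep(m, "variance", "complete", feature_counts = c(50, 100, 200, 400),
                        B = 50, seed = 2)
  expect_true(sw$stable)
  expect_equal(sw$selected_count, 50)
  expect_equal(nrow(sw$curve), 4)
})

test_that("consensus: unanimity, tie rule, and label-swap alignment", {
  labs <- setNames(rep(c(1L, 2L), each = 4), sprintf("s%02d", 1:8))
  same <- list(a = labs, b = labs, c = labs, d = labs)
  cons <- consensus_assignment(same)
  expect_true(all(cons[1:4] == "group1") && all(cons[5:8] == "group2"))
  expect_equal(sum(cons == "unclassifiable"), 0)

  # swapped labels but identical partitions still align perfectly
  swapped <- list(a = labs, b = 3L - labs, c = labs, d = 3L - labs)
  cons2 <- consensus_assignment(swapped)
  expect_identical(as.character(cons2), as.character(cons))

  # 3 vs 3 split on one sample -> unclassifiable
  six <- lapply(1:6, function(i) { l <- labs; if (i <= 3) l["s01"] <- 2L; l })
  names(six) <- letters[1:6]
  cons3 <- consensus_assignment(six)
  expect_equal(as.character(cons3[["s01"]]), "unclassifiable")
  expect_true(all(cons3[-1] != "unclassifiable"))

  bad <- list(a = labs, b = labs[-1])
  expect_error(consensus_assignment(bad), "different sample sets")
})

test_that("marker labeling follows the higher-median cluster and survives relabeling", {
  set.seed(3)
  X <- matrix(rnorm(50 * 10, 5), 50, 10,
              dimnames = list(c("ALK", sprintf("g%03d", 1:49)), sprintf("s%02d", 1:10)))
  X["ALK", 1:5] <- X["ALK", 1:5] + 2
  m <- omics_matrix(X, "log2_expression")
  cons <- factor(rep(c("group1", "group2"), each = 5),
                 levels = c("group1", "group2", "unclassifiable"))
  names(cons) <- colnames(X)
  lab <- label_by_marker(cons, m)
  expect_true(all(lab$labels[1:5] == "ALK_high"))
  expect_true(all(lab$labels[6:10] == "ALK_low"))

  cons_swapped <- factor(ifelse(cons == "group1", "group2", "group1"),
                         levels = levels(cons))
  names(cons_swapped) <- names(cons)
  lab2 <- label_by_marker(cons_swapped, m)
  expect_identical(as.character(lab2$labels), as.character(lab$labels))

  expect_error(label_by_marker(cons, m, marker_gene = "NOPE"), "absent")
  Xt <- X; Xt["ALK", ] <- rep(c(1, 2, 3, 4, 5), 2)
  expect_error(label_by_marker(cons, omics_matrix(Xt, "log2_expression")),
               "tie.*high_group")
})
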