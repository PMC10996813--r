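# Beta/M conversion, probe/sample filters, differential methylation,
# region summarization, beta profiling, ALK-correlation screen.

test_that("beta/M conversion: worked values, strict monotonicity, inverse round-trip", {
  b <- om(matrix(c(0.5, 0.8, 0.2, 0.999), 2, 2), "beta",
          features = c("p1", "p2"), samples = c("s1", "s2"))
  m <- beta_to_m(b)
  expect_equal(m$values["p1", "s1"], 0)
  expect_equal(m$values["p2", "s1"], 2)   # log2(0.8/0.2)
  expect_identical(m$value_kind, "m_value")
  set.seed(2)
  bb <- om(matrix(runif(200), 20, 10), "beta")
  mm <- beta_to_m(bb)
  back <- m_to_beta(mm)
  expect_lt(max(abs(back$values - pmin(pmax(bb$values, 1e-6), 1 - 1e-6))), 1e-9)
  # monotone: order of betas preserved in M within every sample
  for (j in 1:10) expect_identical(order(bb$values[, j]), order(mm$values[, j]))
})

make_meth_fixture <- function() {
  set.seed(44)
  probes <- sprintf("cg%03d", 1:10)
  b <- om(matrix(runif(10 * 6), 10, 6), "beta", features = probes)
  mf <- probe_manifest(data.frame(
    probe_id = probes,
    chrom = c("chrX", "chr2", "chrX", rep("chr5", 7)),
    position = 1:10 * 1000,
    gene = c("", "TP53", "", "ALK", "JUNB", "", "MYC", "DNMT3A", "UHRF1", "CD274"),
    region_class = c("intergenic", "TSS", "gene_body", "gene_body", "TSS",
                     "intergenic", "first_exon", "gene_body", "five_prime_UTR",
                     "three_prime_UTR"),
    snp_vaf = c(0, 0, 0, 0.01, 0.05, 0, 0, 0.2, 0, 0)))
  list(b = b, mf = mf)
}

test_that("probe filter: chrX/Y and SNP removal, boundary rule, order independence", {
  fx <- make_meth_fixture()
  r <- filter_probes(fx$b, fx$mf)
  expect_equal(r$report$chrXY, 2)
  expect_equal(r$report$snp, 2)             # 0.05 and 0.2; 0.01 exactly is kept
  expect_equal(r$report$n_retained, 6)
  expect_true("cg004" %in% feature_ids(r$matrix))  # snp_vaf == cut retained
  # idempotent and order-independent retained set
  r2 <- filter_probes(r$matrix, fx$mf)
  expect_identical(feature_ids(r2$matrix), feature_ids(r$matrix))
  # snp-only filter then chr filter reaches the same set
  only_snp <- fx$mf; only_snp$chrom <- "chr1"
  a <- filter_probes(fx$b, probe_manifest(only_snp))
  bthen <- filter_probes(a$matrix, fx$mf)
  expect_setequal(feature_ids(bthen$matrix), feature_ids(r$matrix))
  # missing manifest entry errors with probe names
  expect_error(filter_probes(fx$b, fx$mf[-1, ]), "cg001")
})

test_that("purity filter: strict < threshold, missing fraction retained with warning", {
  b <- om(matrix(runif(12), 4, 3), "beta", samples = c("sa", "sb", "sc"))
  md <- cohort_metadata(data.frame(
    sample_id = c("sa", "sb", "sc"), timepoint = "diagnosis",
    tumor_fraction = c(0.39, 0.40, NA), survival_time = 1, event = 0))
  expect_warning(r <- filter_samples_by_purity(b, md), "sc")
  expect_identical(sample_ids(r$matrix), c("sb", "sc"))
  expect_identical(r$report$removed, "sa")
  md2 <- md; md2$tumor_fraction <- c(0.9, 0.95, 0.8)
  r2 <- filter_samples_by_purity(b, md2)
  expect_identical(sample_ids(r2$matrix), c("sa", "sb", "sc"))
})

test_that("differential methylation recovers a planted hyper block with correct direction", {
  set.seed(71)
  np <- 1200; n_planted <- 200
  probes <- sprintf("cg%04d", 1:np)
  mu <- rbeta(np, 4, 4)
  bmat <- matrix(NA_real_, np, 16)
  grp <- rep(c("A", "B"), each = 8)
  for (j in 1:16) {
    mj <- mu
    if (grp[j] == "A") mj[1:n_planted] <- pmin(0.95, mj[1:n_planted] + 0.3)
    bmat[, j] <- rbeta(np, mj * 40, (1 - mj) * 40)
  }
  dimnames(bmat) <- list(probes, sprintf("s%02d", 1:16))
  b <- omics_matrix(bmat, "beta")
  m <- beta_to_m(b)
  ga <- sprintf("s%02d", 1:8); gb <- sprintf("s%02d", 9:16)
  dmp <- differential_methylation(m, b, ga, gb)
  hyper_called <- dmp$probe_id[dmp$direction == "hyper"]
  expect_gte(length(intersect(hyper_called, probes[1:n_planted])) / n_planted, 0.9)
  # false calls stay within what BH at q < 0.05 permits
  called <- dmp$probe_id[dmp$direction != "ns"]
  expect_lte(length(setdiff(called, probes[1:n_planted])) / length(called), 0.1)
  # antisymmetry under group swap
  dmp_sw <- differential_methylation(m, b, gb, ga)
  expect_equal(dmp$delta_beta, -dmp_sw$delta_beta, tolerance = 1e-12)
  expect_identical(dmp_sw$direction[dmp$direction == "hyper"][1], "hypo")
  expect_equal(dmp$p, dmp_sw$p, tolerance = 1e-12)
  # two same-distribution groups at n = 3+3 can never clear q < 0.05
  # (the exact two-sided p floors at 0.1), so calls are exactly zero
  dmp0 <- differential_methylation(
    alclomics:::om_subset(m, samples = c(gb[1:3], gb[4:6])),
    alclomics:::om_subset(b, samples = c(gb[1:3], gb[4:6])),
    gb[1:3], gb[4:6])
  expect_true(all(dmp0$direction == "ns"))
  # direction of every called probe agrees in sign with delta_beta
  called <- dmp[dmp$direction != "ns", ]
  expect_true(all(sign(called$delta_beta) == ifelse(called$direction == "hyper", 1, -1)))
})

test_that("per-probe Wilcoxon p-values match the scalar implementation", {
  set.seed(5)
  X <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(sprintf("p%02d", 1:50), sprintf("s%02d", 1:10)))
  ga <- sprintf("s%02d", 1:5); gb <- sprintf("s%02d", 6:10)
  pv <- alclomics:::wilcox_p_rows(X, ga, gb)
  for (i in c(1, 13, 50)) {
    expect_equal(unname(pv[i]),
                 wilcoxon_rank_sum(X[i, ga], X[i, gb], mode = "exact")$p_value,
                 tolerance = 1e-12)
  }
  # large-n path
  X2 <- matrix(rnorm(20 * 30), 20, 30,
               dimnames = list(sprintf("p%02d", 1:20), sprintf("s%02d", 1:30)))
  ga2 <- sprintf("s%02d", 1:15); gb2 <- sprintf("s%02d", 16:30)
  pv2 <- alclomics:::wilcox_p_rows(X2, ga2, gb2)
  expect_equal(unname(pv2[3]),
               wilcoxon_rank_sum(X2[3, ga2], X2[3, gb2], mode = "normal_approx")$p_value,
               tolerance = 1e-12)
})

test_that("region summarization conserves calls and orders gene body first", {
  fx <- make_meth_fixture()
  dmp <- data.frame(probe_id = fx$mf$probe_id,
                    delta_beta = c(.3, .2, -.1, .4, .2, 0, -.3, .1, .2, -.2),
                    p = 0.001, q = 0.01,
                    direction = c("hyper", "hyper", "hypo", "hyper", "hyper",
                                  "ns", "hypo", "hyper", "hyper", "hypo"))
  s <- summarize_regions(dmp, fx$mf)
  expect_equal(sum(s$n_hyper) + sum(s$n_hypo), sum(dmp$direction != "ns"))
  expect_equal(s$n_hyper[s$region_class == "gene_body"], 2)
  # zero calls -> all-zero table
  dmp0 <- transform(dmp, direction = "ns")
  s0 <- summarize_regions(dmp0, fx$mf)
  expect_true(all(s0$n_hyper == 0 & s0$n_hypo == 0))
  expect_error(summarize_regions(dmp, fx$mf[-2, ]), "missing")
})

test_that("beta profile: histogram conservation, mid fraction, bimodality contrast", {
  set.seed(20)
  nlow <- 8; nhigh <- 8; np <- 600
  blow <- matrix(c(rbeta(np * nlow / 2, 2, 18), rbeta(np * nlow / 2, 18, 2)), np, nlow)
  bhigh <- matrix(rbeta(np * nhigh, 10, 10), np, nhigh)
  b <- om(cbind(blow, bhigh), "beta",
          features = sprintf("cg%04d", 1:np),
          samples = sprintf("s%02d", 1:(nlow + nhigh)))
  labs <- setNames(rep(c("low", "high"), c(nlow, nhigh)), sample_ids(b))
  prof <- beta_profile(b, labs)
  expect_equal(sum(prof$low$histogram), np * nlow)
  expect_gt(prof$low$dip, prof$high$dip)
  expect_gt(prof$high$fraction_mid, prof$low$fraction_mid)
  # degenerate constant input
  bc <- om(matrix(0.5, 10, 4), "beta")
  pc <- beta_profile(bc, setNames(rep("g", 4), sample_ids(bc)))
  expect_equal(pc$g$fraction_mid, 1)
  expect_equal(pc$g$dip, 0)
})

test_that("ALK-correlation screen: monotone probe, planted recovery, cutoff edge", {
  set.seed(30)
  n <- 20
  alk <- rnorm(n, 6, 1.5)
  np <- 400
  probes <- sprintf("cg%04d", 1:np)
  M <- matrix(rnorm(np * n), np, n, dimnames = list(probes, sprintf("s%02d", 1:n)))
  M[1, ] <- alk^3                     # perfect monotone tracker
  planted <- 2:41
  for (i in planted) {
    s <- if (i %% 2) 1 else -1
    M[i, ] <- s * 1.3 * scale(alk)[, 1] + rnorm(n, sd = 0.4)
  }
  expr <- om(rbind(ALK = alk, G1 = rnorm(n)), "log2_expression",
             features = c("ALK", "G1"), samples = sprintf("s%02d", 1:n))
  mm <- omics_matrix(M, "m_value")
  mf <- probe_manifest(data.frame(probe_id = probes, chrom = "chr2",
                                  position = seq_len(np), gene = paste0("GENE", seq_len(np)),
                                  region_class = "gene_body", snp_vaf = 0))
  cr <- correlate_with_expression(mm, expr, mf)
  rec <- cr$records
  expect_equal(rec$rho[1], 1)
  expect_true(rec$selected[1] && rec$sign[1] == "positive")
  sel_planted <- rec$selected[planted]
  prec <- sum(rec$selected & seq_len(np) %in% c(1, planted)) / sum(rec$selected)
  expect_gte(mean(sel_planted), 0.8)       # recall
  expect_gte(prec, 0.8)                    # precision
  expect_true(all(c("GENE2", "GENE4") %in% c(cr$positive_genes, cr$negative_genes) ==
                    rec$selected[c(2, 4)]))
  # nothing selected above an impossible cutoff
  cr2 <- correlate_with_expression(mm, expr, mf, rho_cut = 1.01)
  expect_equal(sum(cr2$records$selected), 0)
  expect_error(correlate_with_expression(
    alclomics:::om_subset(mm, samples = sprintf("s%02d", 1:4)), expr, mf),
    ">= 5 shared")
})
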