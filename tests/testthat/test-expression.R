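# Differential expression, relapse signature, ssGSEA, dichotomization.

test_that("differential_expression recovers planted effects with correct direction", {
  m <- planted_matrix(n1 = 10, n2 = 10, n_feat = 1000, n_inf = 100, shift = 2,
                      sd = 0.6, seed = 14, mixed = FALSE)
  ga <- sprintf("s%02d", 1:10); gb <- sprintf("s%02d", 11:20)
  de <- differential_expression(m, ga, gb)
  called_up <- de$feature_id[de$direction == "up"]
  planted <- sprintf("f%03d", 1:100)
  expect_gte(length(intersect(called_up, planted)) / 100, 0.9)   # recall
  expect_equal(length(setdiff(de$feature_id[de$direction != "ns"], planted)), 0)
  # direction accuracy: all calls among planted are "up"
  expect_true(all(de$direction[de$feature_id %in% planted & de$direction != "ns"] == "up"))
})

test_that("differential_expression controls false calls under the null and respects lfc_cut", {
  set.seed(91)
  X <- matrix(rnorm(1000 * 12, 5, 1), 1000, 12,
              dimnames = list(sprintf("g%04d", 1:1000), sprintf("s%02d", 1:12)))
  m <- omics_matrix(X, "log2_expression")
  de <- differential_expression(m, sprintf("s%02d", 1:6), sprintf("s%02d", 7:12))
  expect_lte(attr(de, "n_up") + attr(de, "n_down"), 50)    # <= 5% of features
  de_inf <- differential_expression(m, sprintf("s%02d", 1:6), sprintf("s%02d", 7:12),
                                    lfc_cut = Inf)
  expect_equal(attr(de_inf, "n_up") + attr(de_inf, "n_down"), 0)
  expect_error(differential_expression(m, sprintf("s%02d", 1:6), sprintf("s%02d", 5:12)),
               "overlap")
})

test_that("label swap negates log2fc and preserves p and q exactly", {
  m <- planted_matrix(n1 = 5, n2 = 7, n_feat = 200, n_inf = 40, seed = 3)
  ga <- sprintf("s%02d", 1:5); gb <- sprintf("s%02d", 6:12)
  d1 <- differential_expression(m, ga, gb)
  d2 <- differential_expression(m, gb, ga)
  expect_equal(d1$log2fc, -d2$log2fc, tolerance = 1e-12)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
  expect_equal(d1$q, d2$q, tolerance = 1e-12)
})

test_that("relapse signature: conjunctive thresholds, purity, identical groups empty", {
  co <- simulate_cohort(cohort_spec(n_diagnosis = 32, n_relapse = 4,
                                    n_genes = 1500, n_probes = 50,
                                    n_immune_genes = 50, n_proliferation_genes = 50,
                                    n_relapse_genes = 36, n_hyper_probes = 5, n_hypo_probes = 5,
                                    n_alk_probes = 5, seed = 21))
  sig <- derive_relapse_signature(co$expression, co$truth$relapse_ids,
                                  co$truth$diagnosis_ids)
  genes <- sig$relapse_signature$genes
  expect_gte(length(intersect(genes, co$truth$relapse_genes)) /
               length(co$truth$relapse_genes), 0.8)
  # re-running yields the identical set (pure function)
  sig2 <- derive_relapse_signature(co$expression, co$truth$relapse_ids,
                                   co$truth$diagnosis_ids)
  expect_identical(sig2$relapse_signature$genes, genes)
  # conjunctive: every selected gene satisfies all three thresholds
  de <- attr(sig, "differential")
  sel <- de[de$feature_id %in% genes, ]
  expect_true(all(sel$p < 0.01 & sel$log2fc > 1 & sel$q < 0.25))

  # identical "relapse" and "diagnosis" distributions -> empty signature
  set.seed(10)
  X <- matrix(rnorm(300 * 10, 5), 300, 10,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:10)))
  m <- omics_matrix(X, "log2_expression")
  expect_warning(empty <- derive_relapse_signature(m, sprintf("s%02d", 1:4),
                                                   sprintf("s%02d", 5:10)),
                 "empty")
  expect_length(empty, 0)
})

test_that("ssgsea matches the hand-summed running difference and its extremal case", {
  X <- matrix(c(5, 4, 3, 2, 1,
                1, 5, 2, 4, 3), ncol = 2,
              dimnames = list(c("g1", "g2", "g3", "g4", "g5"), c("sA", "sB")))
  m <- omics_matrix(X, "log2_expression")
  set <- c("g1", "g2")
  sc <- ssgsea_score(m, set)
  for (j in 1:2) {
    expect_equal(unname(sc[j]), ssgsea_hand(X[, j], rownames(X), set),
                 tolerance = 1e-12)
  }
  # sample with all set genes at the top has the maximal score
  expect_gt(sc[["sA"]], sc[["sB"]])
  expect_error(ssgsea_score(m, rownames(X)), "covers every feature")
  expect_error(ssgsea_score(m, c("zz1", "zz2")), "does not intersect")
})

test_that("ssgsea is invariant to per-sample monotone transforms and sample order", {
  set.seed(17)
  X <- matrix(rexp(100 * 6), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:6)))
  m <- omics_matrix(X, "fpkm")
  set <- sprintf("g%03d", c(3, 17, 40, 77))
  s1 <- ssgsea_score(m, set)
  X2 <- X; X2[, 2] <- log1p(X2[, 2]); X2[, 5] <- X2[, 5]^3
  s2 <- ssgsea_score(omics_matrix(X2, "fpkm"), set)
  expect_equal(s1, s2, tolerance = 1e-12)
  perm <- sample(colnames(X))
  s3 <- ssgsea_score(omics_matrix(X[, perm], "fpkm"), set)
  expect_equal(s1[perm], s3, tolerance = 1e-12)
})

test_that("median dichotomization counts, tie rule, and planted relapse recovery", {
  sc <- setNames(c(5, 3, 8, 1, 9, 2, 7), sprintf("s%02d", 1:7))
  card <- dichotomize_by_median(sc, sprintf("s%02d", 1:7))
  expect_equal(sum(card$stratum == "HIGH"), 3)   # floor(7/2)
  all_eq <- dichotomize_by_median(setNames(rep(2, 5), letters[1:5]), letters[1:5])
  expect_true(all(all_eq$stratum == "LOW"))
  expect_error(dichotomize_by_median(sc, character(0)), "empty")

  # diagnosis samples of eventual relapsers score above the diagnosis median
  hits <- 0
  for (seed in 1:10) {
    co <- simulate_cohort(cohort_spec(n_diagnosis = 24, n_relapse = 4,
                                      n_genes = 800, n_probes = 50,
                                      n_immune_genes = 40, n_proliferation_genes = 40,
                                      n_relapse_genes = 36, n_hyper_probes = 5, n_hypo_probes = 5,
                                      n_alk_probes = 5, n_eventual_relapse = 6,
                                      seed = 400 + seed))
    sig <- derive_relapse_signature(co$expression, co$truth$relapse_ids,
                                    co$truth$diagnosis_ids)
    sc <- ssgsea_score(co$expression, sig$relapse_signature$genes)
    card <- dichotomize_by_median(sc, co$truth$diagnosis_ids)
    strat <- setNames(card$stratum, card$sample_id)
    frac_high <- mean(strat[co$truth$eventual_relapsers] == "HIGH")
    if (frac_high > 0.5) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("program scores separate planted immune groups; errors are informative", {
  co <- simulate_cohort(cohort_spec(n_diagnosis = 20, n_relapse = 2,
                                    n_genes = 1000, n_probes = 50,
                                    n_immune_genes = 60, n_proliferation_genes = 60,
                                    n_relapse_genes = 20, n_hyper_probes = 5, n_hypo_probes = 5,
                                    n_alk_probes = 5, seed = 33))
  lib <- gene_set_library(list(immune = co$truth$immune_genes,
                               proliferation = co$truth$proliferation_genes))
  ps <- program_score(co$expression, lib, c("immune", "immune"))
  expect_equal(colnames(ps$scores), "immune")   # duplicate request idempotent
  dg <- co$truth$diagnosis_ids
  lo <- dg[co$truth$group[dg] == "ALK_low"]; hi <- dg[co$truth$group[dg] == "ALK_high"]
  wt <- wilcoxon_rank_sum(ps$summary[lo], ps$summary[hi])
  expect_lt(wt$p_value, 0.01)
  expect_gt(median(ps$summary[lo]), median(ps$summary[hi]))
  expect_error(program_score(co$expression, lib, "nope"), "unknown program")
  lib2 <- gene_set_library(list(ghost = c("NOT1", "NOT2")))
  expect_error(program_score(co$expression, lib2, "ghost"), "no genes")
})
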