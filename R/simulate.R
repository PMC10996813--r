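# Seeded generator of complete synthetic cohorts carrying the statistical
# structure the pipeline assumes: two diagnosis subgroups separated by ALK
# expression and immune/proliferation programs, bimodal-vs-moderate
# methylation marginals with a region-biased planted hypermethylation
# block, probes tracking ALK expression, group-dependent copy-number
# alteration probabilities, and relapse-associated expression shifts tied
# to survival hazard.  The truth block is the test oracle; pipeline stages
# never read it.

#' Specification of a synthetic cohort
#'
#' Defaults are sized to the study design the pipeline targets: 32
#' diagnosis + 4 relapse samples with about 14/32 of the diagnosis cohort
#' in the ALK-high group, 5000 genes, 10000 EPIC-style probes, a 36-gene
#' relapse program, and CN-alteration probabilities of 0.727 vs 0.0625 in
#' the ALK-high vs ALK-low groups.
#'
#' @param n_diagnosis,n_relapse sample counts per timepoint.
#' @param n_genes,n_probes feature counts.
#' @param group_fraction fraction of diagnosis samples planted ALK_high.
#' @param alk_log2_shift planted ALK log2 difference (high minus low).
#' @param n_immune_genes,n_proliferation_genes,n_relapse_genes planted
#'   program sizes (disjoint gene blocks).
#' @param program_log2_shift log2 shift of the immune (up in ALK_low) and
#'   proliferation (up in ALK_high) programs.
#' @param relapse_log2_shift log2 shift of the relapse program in relapse
#'   samples; diagnosis samples of eventual relapsers get half of it.
#' @param n_eventual_relapse number of diagnosis samples planted as
#'   eventual relapsers (elevated relapse program, higher hazard).
#' @param meth_mixture beta-mixture parameters: component \code{weights}
#'   (hypo/hyper/mid), per-component Beta shapes, \code{high_shrink}
#'   (contraction of ALK-high probe means toward 0.5, producing the
#'   moderate mid-centered profile) and \code{concentration} of per-sample
#'   Beta noise around the probe mean.
#' @param n_hyper_probes,n_hypo_probes,delta_hyper planted ALK-low
#'   differential-methylation blocks (hyper- and hypomethylated relative
#'   to ALK-high): sizes and central beta shift; per-probe deltas vary
#'   uniformly in [0.5, 1.25] times \code{delta_hyper} so the planted
#'   pattern is probe-specific rather than a per-sample offset.
#' @param hyper_region_bias named sampling weights over region classes for
#'   the planted block (gene body heaviest).
#' @param n_alk_probes probes whose methylation tracks ALK expression
#'   (half positively, half negatively), for the correlation screen.
#' @param cn_prob_high,cn_prob_low per-group CN-alteration probabilities.
#' @param hazard_ratio hazard of eventual relapsers vs the rest.
#' @param noise_sd log2-scale expression noise (log-normal multiplicative).
#' @param seed integer seed driving every draw.
#' @return a validated list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_diagnosis = 32, n_relapse = 4,
                        n_genes = 5000, n_probes = 10000,
                        group_fraction = 14 / 32,
                        alk_log2_shift = 2,
                        n_immune_genes = 150, n_proliferation_genes = 150,
                        n_relapse_genes = 36,
                        program_log2_shift = 1.5,
                        relapse_log2_shift = 2,
                        n_eventual_relapse = 8,
                        meth_mixture = list(
                          weights = c(hypo = 0.45, hyper = 0.45, mid = 0.10),
                          hypo = c(2, 18), hyper = c(18, 2), mid = c(8, 8),
                          high_shrink = 0.3, concentration = 30),
                        n_hyper_probes = 500, n_hypo_probes = 150,
                        delta_hyper = 0.3,
                        hyper_region_bias = c(TSS = 0.20, five_prime_UTR = 0.05,
                                              first_exon = 0.05, gene_body = 0.55,
                                              three_prime_UTR = 0.05,
                                              intergenic = 0.10),
                        n_alk_probes = 50,
                        cn_prob_high = 0.727, cn_prob_low = 0.0625,
                        hazard_ratio = 3,
                        noise_sd = 0.5,
                        seed = 1) {
  spec <- mget(names(formals(cohort_spec)))
  fracs <- c(group_fraction = group_fraction, cn_prob_high = cn_prob_high,
             cn_prob_low = cn_prob_low)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0,1]: ",
         paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "), call. = FALSE)
  }
  if (n_diagnosis < 1 || n_genes < 1 || n_probes < 1 || n_relapse < 0) {
    stop("cohort and feature sizes must be positive (n_relapse may be 0)",
         call. = FALSE)
  }
  if (1 + n_immune_genes + n_proliferation_genes + n_relapse_genes > n_genes) {
    stop("planted gene programs (plus ALK) exceed n_genes", call. = FALSE)
  }
  if (n_hyper_probes + n_hypo_probes + n_alk_probes > n_probes) {
    stop("planted probe programs exceed n_probes", call. = FALSE)
  }
  if (n_eventual_relapse > n_diagnosis) {
    stop("n_eventual_relapse exceeds n_diagnosis", call. = FALSE)
  }
  structure(spec, class = "cohort_spec")
}

#' Simulate a complete synthetic cohort
#'
#' Draws expression (FPKM), methylation (beta) with an EPIC-style
#' manifest, metadata with survival, copy-number segments and a mutation
#' table from a \code{\link{cohort_spec}}, together with the planted
#' truth.  All randomness comes from \code{spec$seed}; the same spec gives
#' a bit-identical cohort.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list of class \code{synthetic_cohort}: \code{expression},
#'   \code{methylation} (\code{\link{omics_matrix}}es), \code{manifest},
#'   \code{metadata}, \code{segments}, \code{mutations}, \code{truth}
#'   (planted labels and feature lists), \code{spec}.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, simulate_cohort_impl(spec))
}

simulate_cohort_impl <- function(spec) {
  nd <- spec$n_diagnosis; nr <- spec$n_relapse
  diag_ids <- sprintf("D%02d", seq_len(nd))
  rel_ids <- if (nr > 0) sprintf("R%02d", seq_len(nr)) else character(0)
  ids <- c(diag_ids, rel_ids)
  n <- length(ids)

  # planted subgroups
  n_high <- round(spec$group_fraction * nd)
  group_d <- sample(rep(c("ALK_high", "ALK_low"), c(n_high, nd - n_high)))
  group_r <- sample(c("ALK_high", "ALK_low"), nr, replace = TRUE,
                    prob = c(spec$group_fraction, 1 - spec$group_fraction))
  group <- setNames(c(group_d, group_r), ids)
  is_high <- group == "ALK_high"
  relapsers <- sample(diag_ids, spec$n_eventual_relapse)

  # gene universe and planted programs
  genes <- c("ALK", sprintf("G%04d", seq_len(spec$n_genes - 1)))
  off <- 1
  immune <- genes[off + seq_len(spec$n_immune_genes)]
  off <- off + spec$n_immune_genes
  prolif <- genes[off + seq_len(spec$n_proliferation_genes)]
  off <- off + spec$n_proliferation_genes
  relapse_genes <- genes[off + seq_len(spec$n_relapse_genes)]

  # expression: baseline log2 means + planted shifts + log-normal noise
  mu <- rnorm(spec$n_genes, mean = 3, sd = 1.5)
  names(mu) <- genes
  mu["ALK"] <- 5
  z <- matrix(mu, nrow = spec$n_genes, ncol = n) +
       matrix(rnorm(spec$n_genes * n, sd = spec$noise_sd), spec$n_genes, n)
  dimnames(z) <- list(genes, ids)
  z["ALK", is_high] <- z["ALK", is_high] + spec$alk_log2_shift
  z[immune, !is_high] <- z[immune, !is_high] + spec$program_log2_shift
  z[prolif, is_high] <- z[prolif, is_high] + spec$program_log2_shift
  if (nr > 0) z[relapse_genes, rel_ids] <- z[relapse_genes, rel_ids] + spec$relapse_log2_shift
  z[relapse_genes, relapsers] <- z[relapse_genes, relapsers] + 0.5 * spec$relapse_log2_shift
  expression <- omics_matrix(pmax(2^z - 1, 0), "fpkm")

  # survival: exponential with planted hazard ratio for eventual
  # relapsers (and relapse-timepoint samples); uniform censoring
  base_rate <- 0.08
  rate <- ifelse(ids %in% c(relapsers, rel_ids), base_rate * spec$hazard_ratio,
                 base_rate)
  t_event <- rexp(n, rate)
  t_cens <- runif(n, 2, 12)
  survival_time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  # purity: most samples clean, about 1 in 7 below the 40% threshold
  tumor_fraction <- rbeta(n, 9, 3)
  n_low <- max(1, round(n / 7))
  low_purity <- sample(ids, n_low)
  tumor_fraction[match(low_purity, ids)] <- runif(n_low, 0.15, 0.39)

  histology <- sample(HISTOLOGIES[1:3], n, replace = TRUE,
                      prob = c(0.85, 0.075, 0.075))
  cn_altered <- rbinom(n, 1, ifelse(is_high, spec$cn_prob_high, spec$cn_prob_low)) == 1

  metadata <- cohort_metadata(data.frame(
    sample_id = ids,
    timepoint = rep(c("diagnosis", "relapse"), c(nd, nr)),
    tumor_fraction = tumor_fraction,
    survival_time = survival_time,
    event = event,
    histology = histology,
    cn_altered = cn_altered,
    stringsAsFactors = FALSE))

  # manifest: autosomes mostly, some chrX/Y and SNP probes to exercise
  # the filters; genes attached except for intergenic probes
  np <- spec$n_probes
  probes <- sprintf("cg%06d", seq_len(np))
  chrom <- sample(paste0("chr", 1:22), np, replace = TRUE)
  xy <- sample.int(np, round(0.04 * np))
  chrom[xy] <- sample(c("chrX", "chrY"), length(xy), replace = TRUE,
                      prob = c(0.75, 0.25))
  region_class <- sample(REGION_CLASSES, np, replace = TRUE,
                         prob = c(0.20, 0.08, 0.07, 0.40, 0.10, 0.15))
  gene <- ifelse(region_class == "intergenic", "",
                 sample(genes, np, replace = TRUE))
  snp_vaf <- numeric(np)
  snpy <- sample.int(np, round(0.05 * np))
  snp_vaf[snpy] <- runif(length(snpy), 0, 0.1)
  manifest <- probe_manifest(data.frame(
    probe_id = probes, chrom = chrom, position = sample.int(2.4e8, np, replace = TRUE),
    gene = gene, region_class = region_class, snp_vaf = snp_vaf,
    stringsAsFactors = FALSE))

  # probes eligible for planted structure must survive the filters
  eligible <- which(!chrom %in% c("chrX", "chrY") & snp_vaf <= 0.01)
  alk_idx <- sample(eligible, spec$n_alk_probes)
  remaining <- setdiff(eligible, alk_idx)
  bias_w <- spec$hyper_region_bias[region_class[remaining]]
  hyper_idx <- sample(remaining, spec$n_hyper_probes, prob = bias_w)
  remaining2 <- setdiff(remaining, hyper_idx)
  hypo_idx <- if (spec$n_hypo_probes > 0) {
    sample(remaining2, spec$n_hypo_probes,
           prob = spec$hyper_region_bias[region_class[remaining2]])
  } else integer(0)

  # beta values: probe means from a hypo/hyper/mid mixture; ALK-high
  # means shrunk toward 0.5 (moderate profile), ALK-low means kept
  # (bimodal profile); planted block shifted up in ALK-low
  mm <- spec$meth_mixture
  comp <- sample(c("hypo", "hyper", "mid"), np, replace = TRUE, prob = mm$weights)
  mu_p <- numeric(np)
  for (cp in c("hypo", "hyper", "mid")) {
    sel <- comp == cp
    mu_p[sel] <- rbeta(sum(sel), mm[[cp]][1], mm[[cp]][2])
  }
  # ALK-high profiles compress toward intermediate methylation with a
  # probe-specific retention factor (a uniform factor would be an affine
  # per-sample transform, invisible to the correlation distance); at
  # high_shrink >= 1 the compression is disabled and the groups share means
  shrink_p <- if (mm$high_shrink >= 1) rep(1, np) else {
    runif(np, max(0, mm$high_shrink - 0.25), min(1, mm$high_shrink + 0.25))
  }
  mean_high <- 0.5 + shrink_p * (mu_p - 0.5)
  mean_low <- mu_p
  # planted differential blocks: heterogeneous per-probe deltas, so the
  # ALK-low-specific pattern is not a per-sample affine shift (which a
  # correlation distance could never see)
  d_hyper <- spec$delta_hyper * runif(length(hyper_idx), 0.5, 1.25)
  mean_low[hyper_idx] <- pmin(0.97, mean_high[hyper_idx] + d_hyper)
  d_hypo <- spec$delta_hyper * runif(length(hypo_idx), 0.5, 1.25)
  mean_low[hypo_idx] <- pmax(0.03, mean_high[hypo_idx] - d_hypo)
  k <- mm$concentration
  beta <- matrix(NA_real_, np, n, dimnames = list(probes, ids))
  for (j in seq_len(n)) {
    mj <- if (is_high[j]) mean_high else mean_low
    beta[, j] <- rbeta(np, mj * k, (1 - mj) * k)
  }
  # ALK-tracking probes: methylation follows the sample's ALK expression
  alk_z <- as.numeric(scale(z["ALK", ]))
  alk_sign <- rep(c(1, -1), length.out = spec$n_alk_probes)
  for (t in seq_along(alk_idx)) {
    latent <- alk_sign[t] * 1.2 * alk_z + rnorm(n, sd = 0.35) +
      rnorm(1, sd = 0.5)
    beta[alk_idx[t], ] <- stats::plogis(latent)
  }
  methylation <- omics_matrix(beta, "beta")

  # copy-number segments: altered samples carry gain/loss segments
  seg_rows <- list()
  for (j in seq_len(n)) {
    nseg <- 1 + rpois(1, 1)
    for (s in seq_len(nseg)) {
      pos <- sort(sample.int(2e8, 2))
      if (cn_altered[j]) {
        call <- sample(c("gain", "loss"), 1)
        lr <- sample(c(1, -1), 1) * runif(1, 0.4, 1)
        if (call == "loss") lr <- -abs(lr) else lr <- abs(lr)
      } else {
        call <- "neutral"; lr <- rnorm(1, 0, 0.05)
      }
      seg_rows[[length(seg_rows) + 1]] <- data.frame(
        sample_id = ids[j], chrom = sample(paste0("chr", 1:22), 1),
        start = pos[1], end = pos[2], log2_ratio = lr, call = call,
        stringsAsFactors = FALSE)
    }
  }
  segments <- segment_table(do.call(rbind, seg_rows))

  # mutation carrier table
  n_mut <- rpois(n, 3)
  mut_rows <- lapply(seq_len(n), function(j) {
    if (n_mut[j] == 0) return(NULL)
    data.frame(sample_id = ids[j],
               gene = sample(genes, n_mut[j]),
               protein_change = sprintf("p.%s%d%s",
                                        sample(LETTERS, n_mut[j], TRUE),
                                        sample.int(900, n_mut[j], TRUE),
                                        sample(LETTERS, n_mut[j], TRUE)),
               variant_class = sample(c("missense", "nonsense", "frameshift",
                                        "splice"), n_mut[j], TRUE,
                                      prob = c(0.7, 0.1, 0.1, 0.1)),
               vaf = runif(n_mut[j], 0.05, 0.6),
               stringsAsFactors = FALSE)
  })
  mutations <- mutation_table(do.call(rbind, mut_rows[!vapply(mut_rows, is.null, TRUE)]))

  truth <- list(group = group,
                diagnosis_ids = diag_ids, relapse_ids = rel_ids,
                eventual_relapsers = relapsers,
                immune_genes = immune, proliferation_genes = prolif,
                relapse_genes = relapse_genes,
                hyper_probes = probes[hyper_idx],
                hypo_probes = probes[hypo_idx],
                alk_probes = data.frame(probe_id = probes[alk_idx],
                                        sign = ifelse(alk_sign > 0, "positive",
                                                      "negative"),
                                        stringsAsFactors = FALSE),
                cn_altered = setNames(cn_altered, ids))
  log_stage("simulate", sprintf("%d+%d samples, %d genes, %d probes, seed=%d",
                                nd, nr, spec$n_genes, np, spec$seed))
  structure(list(expression = expression, methylation = methylation,
                 manifest = manifest, metadata = metadata,
                 segments = segments, mutations = mutations,
                 truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to a directory
#'
#' Emits every pipeline input file (expression, methylation, manifest,
#' metadata, segments, mutations) plus truth tables.  Truth files are for
#' evaluation only; no pipeline stage reads them.
#'
#' @param cohort a \code{\link{simulate_cohort}} result.
#' @param directory output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  paths <- c(
    expression = write_matrix(cohort$expression, p("expression.tsv")),
    methylation = write_matrix(cohort$methylation, p("methylation.tsv")),
    manifest = write_manifest(cohort$manifest, p("manifest.tsv")),
    metadata = write_metadata(cohort$metadata, p("metadata.tsv")),
    segments = write_segments(cohort$segments, p("segments.tsv")),
    mutations = write_mutations(cohort$mutations, p("mutations.tsv")))
  tr <- cohort$truth
  truth_samples <- data.frame(
    sample_id = names(tr$group), group = unname(tr$group),
    eventual_relapser = names(tr$group) %in% tr$eventual_relapsers,
    cn_altered = unname(tr$cn_altered[names(tr$group)]),
    stringsAsFactors = FALSE)
  write.table(truth_samples, p("truth_samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_features <- rbind(
    data.frame(feature_id = tr$immune_genes, role = "immune_gene"),
    data.frame(feature_id = tr$proliferation_genes, role = "proliferation_gene"),
    data.frame(feature_id = tr$relapse_genes, role = "relapse_gene"),
    data.frame(feature_id = tr$hyper_probes, role = "hyper_probe"),
    data.frame(feature_id = tr$hypo_probes, role = "hypo_probe"),
    data.frame(feature_id = tr$alk_probes$probe_id,
               role = paste0("alk_probe_", tr$alk_probes$sign)))
  write.table(truth_features, p("truth_features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, truth_samples = p("truth_samples.tsv"),
             truth_features = p("truth_features.tsv"))
  invisible(paths)
}
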