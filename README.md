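# alclomics

Multi-omic subtyping and relapse-risk analysis for pediatric ALK-positive
anaplastic large cell lymphoma (ALCL), packaged as tested, reusable R
functions.

ALK+ ALCL cohorts split into two molecular subgroups: **ALK-high**
(higher ALK transcript, MYC/E2F-style proliferative programs, frequent
copy-number alterations) and **ALK-low** (immune/cytokine programs,
genome-wide hypermethylation with a bimodal beta-value distribution).
A transcriptional signature derived from relapse specimens, scored per
sample, is elevated at diagnosis in patients who eventually relapse.
`alclomics` implements that analysis end to end for anyone with a gene ×
sample FPKM matrix, an EPIC-style beta matrix plus probe manifest, and
sample metadata — and ships a seeded synthetic-cohort generator so the
whole pipeline is testable without controlled-access patient data.

## What it computes

* **Subgroup discovery** (`cluster_subtypes`): features ranked by MAD,
  variance and the Hartigan–Hartigan dip statistic
  (D = min over unimodal CDFs U of sup |Fₙ − U|, implemented exactly);
  hierarchical clustering on d = 1 − Pearson correlation under complete
  and average linkage; a bootstrap feature-stability sweep that selects
  the smallest feature count whose two-group partition is reproduced in
  ≥ 70% of feature resamples; strict-majority consensus across the six
  statistic × linkage methods; ALK-marker orientation of the groups.
* **Differential expression** (`differential_expression`): empirical-Bayes
  moderated t with method-of-moments prior on log s², BH adjustment,
  calls at |log₂FC| > 1 and q < 0.05.
* **Relapse signature and outcome** (`derive_relapse_signature`,
  `ssgsea_score`, `dichotomize_by_median`, `survival_by_stratum`):
  relapse-vs-diagnosis genes at raw p < 0.01, log₂FC > 1, q < 0.25;
  per-sample ssGSEA scores (rank-weighted ECDF difference, α = 0.75);
  HIGH/LOW split at the diagnosis-sample median; Kaplan–Meier curves and
  log-rank test.
* **Methylation analysis** (`beta_to_m`, `filter_probes`,
  `filter_samples_by_purity`, `differential_methylation`,
  `summarize_regions`, `beta_profile`, `correlate_with_expression`):
  M = log₂(β/(1−β)); removal of chrX/Y and SNP (VAF > 0.01) probes and
  sub-40%-purity samples; probe-wise exact/approximate Wilcoxon tests on
  M-values with delta-beta effect sizes and region-class summaries;
  pooled beta histograms with a dip-based bimodality index; Spearman
  screening of probes against ALK expression at |ρ| ≥ 0.75.
* **Integration** (`concordance`, `cn_enrichment`, `over_representation`):
  cross-platform label concordance with Fisher's exact test,
  copy-number × subgroup enrichment, one-sided Fisher
  over-representation of gene lists against GMT libraries.
* **Synthetic cohorts** (`cohort_spec`, `simulate_cohort`,
  `write_cohort`): seeded cohorts with planted subgroups, programs,
  methylation structure, CN probabilities and survival hazards, plus the
  ground truth for recovery testing.

All statistical primitives (dip, Spearman, exact Wilcoxon, Fisher 2×2,
BH, moderated t, signal-to-noise, Kaplan–Meier, log-rank) are implemented
in the package and validated in the test suite against independent
oracles (LP minimization, enumeration, base R, `survival`, `limma`).

## Worked example

```r
library(alclomics)

co <- simulate_cohort(cohort_spec(seed = 42))      # 32 diagnosis + 4 relapse
dg <- co$truth$diagnosis_ids

cl <- cluster_subtypes(alclomics:::om_subset(co$expression, samples = dg),
                       marker_gene = "ALK", B = 100, seed = 7)
cl
#> cluster_outcome:
#>   mad_complete       count= 250 support=1.00
#>   mad_average        count= 250 support=1.00
#>   variance_complete  count= 250 support=1.00
#>   variance_average   count= 250 support=1.00
#>   dip_complete       count= 250 support=1.00
#>   dip_average        count= 250 support=1.00
#>   consensus: ALK_high=14 ALK_low=18 unclassifiable=0
```

Every method combination reaches full bootstrap support at the smallest
feature count, and the consensus recovers a 14/18 split with no
unclassifiable samples.  Downstream:

```r
hi <- names(cl$labels)[cl$labels == "ALK_high"]
lo <- names(cl$labels)[cl$labels == "ALK_low"]
de <- differential_expression(co$expression, hi, lo)
c(up = attr(de, "n_up"), down = attr(de, "n_down"))
#>   up down
#>  150  146

sig <- derive_relapse_signature(co$expression, co$truth$relapse_ids, dg)
length(sig$relapse_signature$genes)
#> [1] 38

scores <- ssgsea_score(co$expression, sig$relapse_signature$genes)
card <- dichotomize_by_median(scores, dg)
sv <- survival_by_stratum(co$metadata, setNames(card$stratum, card$sample_id)[dg])
sv$logrank
#> log-rank: statistic = 1.21493, p = 0.2704
```

The 150/146 differential calls are the planted immune and proliferation
programs (150 genes each); the 38-gene signature contains all 36 planted
relapse genes; the log-rank p reflects the modest power of a 32-sample
split, as in real cohorts of this size.

A command-line wrapper with `simulate`, `cluster`, `de`, `relapse-score`,
`gsea`, `dmr`, `correlate`, `integrate` and `survival` subcommands is
installed at `system.file("cli/alclomics-cli.R", package = "alclomics")`.

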