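# tmecontext

Immune-contexture analysis of bulk lymphoma transcriptomes.

Primary central nervous system lymphoma and related B-cell malignancies
differ sharply in how much immune infiltrate their tumor microenvironment
(TME) holds, and that contexture tracks both antigen-presentation status
and patient outcome. `tmecontext` is an R package for researchers who have
bulk expression data — RNA-seq normalized counts and/or probe-level
microarray intensities — and want to stratify samples by immune contexture
and relate that stratification to signaling and survival. It provides:

* **Signature scoring** — per-gene z-scores (sample sd, counts
  log2(x+1)-transformed) averaged over gene sets:
  score(S, s) = mean over g in S of z_gs; plus an aggregate infiltration
  score (sum of the immune signature scores).
* **Immune subtyping** — Ward/Euclidean clustering of samples on T-cell
  signature scores into immune-rich / intermediate / poor, with a
  deterministic cluster-naming rule (highest mean activated-CD8 score is
  rich, lowest mean total T-cell score is poor).
* **HLA class I/II status** — per-gene median dichotomization (strictly
  below median = low), Ward clustering of the binary matrix into four
  clusters named normal / I-down / II-down / I&II-down.
* **Differential expression** — pluggable two-group test (Wilcoxon
  rank-sum default) behind the quadruple filter p < 0.01, FDR < 0.01,
  fold-change >= 2, mean normalized counts >= 20.
* **Enrichment** — upper-tail hypergeometric ORA with per-collection
  minimum overlap, and preranked GSEA (weighted KS running sum, gene-label
  permutation null, NES, joint BH across the collection).
* **Ligand-receptor inference** — per-pair Spearman with the probe-max
  rule on microarrays, confident-pair selection at a threshold tau,
  cross-platform consensus minus background pairs (the logged funnel),
  per-sample L-R scores sqrt(L*R)/(sqrt(L*R)+mu), and an
  infiltration-correlation screen (rho > 0.5, FDR < 0.05).
* **Statistics** — Fisher exact (2x2), Pearson chi-squared without
  continuity correction, BH-adjusted Spearman families, Kaplan-Meier,
  log-rank, median splits.
* **Synthetic cohorts** — a generator that plants immune subtypes, HLA
  status, infiltration-driven L-R pairs and subtype-linked survival, with
  full ground truth, so every estimator is validated by recovery tests.

## Worked example

```r
library(tmecontext)

# a two-platform synthetic cohort with planted structure
co <- generate_cohort(cohort_config(seed = 1))

# score signatures and assign immune subtypes
sc <- score_signatures(zscore_matrix(co$expr), co$signatures)
st <- assign_immune_subtypes(sc, synthetic_tcell_signatures(),
                             cd8_signature = "Activated_CD8_T_cells", k = 3)
table(st$subtype)
#> immune_intermediate         immune_poor         immune_rich
#>                  24                  10                  20

# survival: immune-rich versus the rest, relapse-free survival
grp <- ifelse(co$truth$subtype[co$clinical$sample_id] == "rich", "rich", "other")
logrank_test(co$clinical$rfs_time, co$clinical$rfs_event, grp)
#> statistic 8.36, df 1, p 0.00384
```

The subtype table recovers the planted 10/24/20 split exactly, and the
log-rank test shows the planted survival advantage of the immune-rich group
(hazard ratio 0.3 in the generator): immune-rich samples relapse later.

Cohort-level association statistics recompute from cross-tabulated counts
shipped with the package:

```r
tabs <- read_contingency_tables(
  system.file("extdata", "clinical_association_counts.tsv", package = "tmecontext"))
fisher_exact_2x2(tabs$hla_normal_by_subtype, "greater")   # 0.00109
chi2_test(tabs$relapse_rnaseq)$p_value                    # 0.11
```

The Fisher test quantifies the enrichment of immune-rich tumors in the
HLA-normal cluster (10 of 13 HLA-normal samples are immune-rich, against
10 of 41 elsewhere); the chi-squared line tests relapse against the three
subtypes.

The whole analysis also runs as one pipeline from a single configuration
(`run_pipeline(list(synth = list(seed = 1), gsea = list(n_perm = 1000,
seed = 101)), "out/")`), writing subtype, HLA, score, DE, enrichment, L-R
and survival tables plus a `run.log` of every parameter; a thin CLI lives
in `inst/cli/tmecontext`.

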