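# gdtec

Multi-omics fusion for cancer subtyping based on the **driving
relationship between genome and transcriptome**. Somatic mutation,
copy-number and tumor-versus-normal expression-change profiles are
discretized per gene and patient, then fused into one binary matrix of
genome-driven transcriptome expression (GDTEC): a cell is 1 when the
expression change co-occurs concordantly with a copy-number change, or
co-occurs with a somatic mutation — but not both at once. Molecular
subtypes are identified by resampling consensus clustering of the fused
matrix, and the fused features feed Cox proportional-hazards risk models
and random-forest subtype classifiers. A synthetic-cohort generator with
planted subtypes, driven-gene signatures and survival effects makes the
whole pipeline testable end to end.

The package is aimed at computational-oncology analysts who have
harmonized MAF-style mutation calls, GISTIC-style copy-number calls and
normalized expression (e.g. FPKM-UQ) for a tumor cohort with matched
normals and survival follow-up.

## The method in brief

For gene *g* and patient *s*, with ternary layers
*C(g,s)* ∈ {−1,0,1} (copy-number direction) and
*R(g,s)* ∈ {−1,0,1} (expression change, LFC thresholded at the open
normal band (−1, 1)), and the binary mutation layer *S(g,s)*:

- CNV consistency: `CR = 1{C + R ∈ {−2, +2}}` (concordant direction)
- SNV consistency: `SR = S · |R|` (mutated *and* differentially expressed)
- Fusion: `GDTEC = 1{CR + SR = 1}` (XOR; simultaneous driving by both
  mechanisms is treated as noise)
- Filter: drop genes that are 0 in strictly more than 60% of patients.

Subtypes come from subsampled consensus clustering (default: PAM on the
asymmetric-binary/Jaccard distance, 1000 × 80% resampling), with the
number of clusters chosen at the inflection of the consensus-CDF
delta-area curve. Risk models are Cox fits on the GDTEC indicators of
selected genes, with median-split stratification; classifiers are random
forests with mean-decrease-Gini feature selection. See the methods
vignette (`vignettes/gdtec-methods.Rmd`) for the full account.

## Worked example

```r
library(gdtec)

cohort <- generate_cohort(synthetic_spec(seed = 1))
lfc    <- compute_lfc(cohort$expr_tumor, cohort$expr_normal)
fused  <- gdtec(cohort$mutation, collapse_cnv(cohort$cnv_calls),
                discretize_lfc(lfc))
fused
#> GDTEC fusion matrix: 63 genes x 200 samples (17 genes removed by the 60% sparsity filter)
#> driven cells: 5398 (42.8% of retained cells)

run <- consensus_cluster(fused$matrix, k_range = 2:6, reps = 250, seed = 2)
run
#> Consensus clustering (pam/binary, 250 reps, 80% subsampling)
#> k evaluated: 2, 3, 4, 5, 6; chosen k = 4
#> cluster sizes at chosen k:
#>  1  2  3  4
#> 50 50 50 50

truth_ari(run$partition, cohort)     # agreement with the planted subtypes
#> [1] 1

km_logrank(cohort$clinical$os_time, cohort$clinical$os_event,
           run$partition[cohort$clinical$sample_id])
#> Log-rank: chi-square = 65.16 on 3 df, p = 4.644e-14
```

The chosen k equals the four planted subtypes, the partition matches them
exactly (adjusted Rand index 1), and overall survival separates sharply
across the recovered subtypes. A two-gene risk model on the fused
indicators of the cohort's planted risk genes:

```r
feats <- as.data.frame(t(fused$fused[c("G061", "G062"),
                                     cohort$clinical$sample_id]))
fit <- cox_fit(cohort$clinical$os_time, cohort$clinical$os_event, feats)
fit
#> Cox proportional hazards (multivariate, ties = efron): n = 200, events = 158
#>  feature   coef    hr hr_lower hr_upper    z         p
#>     G061 0.7206 2.056    1.399    3.021 3.67 2.421e-04
#>     G062 0.9448 2.572    1.705    3.882 4.50 6.787e-06

km_logrank(cohort$clinical$os_time, cohort$clinical$os_event,
           risk_stratify(fit))
#> Log-rank: chi-square = 44.96 on 1 df, p = 2.011e-11
```

The estimated log hazard ratios (0.72, 0.94) recover the planted effects
(0.7, 0.5) within sampling error, and the median risk split separates
survival. `run_pipeline(list(output_dir = "run1", seed = 1))` performs
the same stages end to end from one configuration (YAML accepted) and
writes fixed-name outputs plus a JSON manifest;
`inst/scripts/gdtec-run.R` wraps it for shell use.

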