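# estroclass

Stratification of ER+ breast tumors by estrogen-independent gene expression.

Estrogen-receptor-positive (ER+) breast cancer is biologically and
clinically heterogeneous, but its transcriptome is dominated by estrogen
signalling, which masks other axes of variation. `estroclass` implements a
framework that removes the estrogen-driven component empirically and
stratifies ER+ tumors on what remains:

1. **b/w scoring.** On a cohort of tumors profiled before and after
   estrogen deprivation, each gene gets a score `b/w`, where
   `b = Var_t(pair means)` is the between-tumor variance and
   `w = mean_t((pre − post)² / 2)` the mean within-pair variance. Genes
   with high scores vary between tumors but ignore estrogen deprivation —
   they report estrogen-independent biology. The top 1,000 form the
   discovery panel.
2. **Consensus NMF class discovery.** The panel-restricted expression
   matrix is factorized as `V ≈ WH` (generalized Kullback–Leibler
   divergence, multiplicative updates) many times per candidate rank
   k = 2–10; co-clustering frequencies form a consensus matrix whose
   cophenetic coefficient measures stability. The most stable rank defines
   the subgroups.
3. **Subgroup classifier.** A nearest-shrunken-centroid (PAM) model is
   trained on the consensus labels, reduced to the top 50 markers per
   subgroup, and classifies new cohorts with posterior probabilities; calls
   with posterior > 0.80 are flagged confident.
4. **Molecular subtyping.** Nearest-centroid assignment by Pearson
   correlation against a user-supplied intrinsic-subtype centroid table.
5. **Survival.** Kaplan–Meier estimation at a 10-year horizon, multi-group
   log-rank tests, O/E hazard ratios `HR = (O_a/E_a)/(O_b/E_b)`, and a
   5-year landmark analysis separating early from late follow-up.

A synthetic cohort generator with planted ground truth (paired
invariant/responsive gene blocks; subgroups with signature genes and
exponential survival) makes the whole pipeline testable end to end. See
`vignettes/estroclass-methods.Rmd` for the model details and design
choices.

## Worked example

Discovery on a synthetic bundle — a paired pre/post cohort to rank genes,
and a 120-tumor cohort with three planted subgroups to discover:

```r
library(estroclass)

paired <- generate_paired_cohort(paired_cohort_spec(
  n_tumors = 30, n_invariant_genes = 60, n_responsive_genes = 60,
  n_noise_genes = 180, seed = 1))
bw <- compute_bw_scores(paired$expr, paired$design)
head(bw[, c("feature_id", "b", "w", "score", "rank")], 3)
#>   feature_id    b     w score rank
#> 1   INV00015 7.32 0.160  45.7    1
#> 2   INV00034 7.00 0.177  39.5    2
#> 3   INV00021 5.25 0.135  38.9    3
```

The top-scoring genes are planted invariant genes: variable between tumors
(`b` ≈ 5–7) yet stable under treatment (`w` ≈ 0.15). Running the full
discovery workflow on a cohort whose subgroup signatures live on those
invariant genes:

```r
disc <- generate_subtyped_cohort(subtyped_cohort_spec(
  n_samples = 120, k_true = 3, n_signature_genes_per_group = 20,
  n_noise_genes = 240, signature_effect = 2, noise_sd = 1,
  survival_scales_years = c(4, 10, 25), seed = 2))
inv <- names(paired$gene_truth)[paired$gene_truth == "invariant"]
rownames(disc$expr$values) <- c(inv, setdiff(feature_ids(paired$expr), inv))

cfg <- pipeline_config(n_top_features = 60, k_min = 2, k_max = 5,
                       n_runs = 20, n_markers_per_class = 10,
                       nmf_max_iter = 300L, seed = 3)
res <- run_discovery(paired$expr, paired$design, disc$expr, cfg)
res$consensus
#> nmf_consensus: ranks 2-5, 20 runs per rank
#>  k cophenetic
#>  2     0.9675
#>  3     1.0000
#>  4     0.9996
#>  5     0.9972
#> selected k = 3
```

The cophenetic coefficient is exactly 1 at the planted rank: every one of
the 20 NMF restarts produced the same 3-way partition. The subgroups carry
their planted survival differences:

```r
subgroup_survival(disc$clinical, res$labels, horizon = 10)
#> subgroup survival (horizon 10 years)
#>  subgroup  n events surv_at_horizon
#>         1 40     37           0.075
#>         2 40     18           0.550
#>         3 40     25           0.375
#> log-rank: chi-square = 34.16 on 2 df, p = 3.819e-08
```

Subgroup 1 (planted mean event time 4 years) has 7.5% 10-year
metastasis-free survival versus 55% in the best group; the omnibus
log-rank test rejects equality decisively. `run_validation()` then
standardizes held-out cohorts, classifies them with the marker-panel model
(`predict()` reports per-class posteriors and confident flags) and repeats
the survival comparison, including the treated-vs-untreated landmark
analysis within each subgroup.

A thin command-line front end over these functions ships in
`inst/cli/estroclass` (subcommands `simulate`, `bw-score`, `discover`,
`classify`, `survival`, `run-all`).

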