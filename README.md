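# tmecausal

Discovery of tumor-microenvironment (TME) related prognostic biomarkers
from bulk tumor RNA-seq and clinical data, with causal effect estimates for
a binary mortality endpoint. The package is aimed at biostatisticians and
computational biologists analyzing TCGA-style cohorts (the motivating
application is ovarian serous cancer 3-year mortality) who want to go
beyond crude logistic associations to confounder-adjusted, doubly robust
effect estimates per gene.

## What it computes

The pipeline chains seven stages, each also usable on its own:

1. **Cohort**: join counts and clinical tables, keep primary tumors, define
   the binary endpoint Y = 1 for death before the horizon (default 3
   years), Y = 0 for survival past it; alive patients with shorter
   follow-up are excluded with itemized reasons.
2. **TME scoring**: per-sample single-sample rank-based enrichment
   (ssGSEA-style, ESTIMATE-like) of immune and stromal signatures on
   log2-CPM expression; combined score = immune + stromal; median split
   into high/low groups.
3. **Differential expression**: per-gene negative-binomial Wald tests
   (median-of-ratios size factors, trend-shrunk method-of-moments
   dispersions) between high/low groups of each score; DEGs at
   |log2FC| > 1.5 and BH FDR < 0.05; the shared, direction-concordant
   intersection of the immune and stromal DEG lists.
4. **Screening**: univariate logistic regression of Y on each
   median-dichotomized DEG and each clinical factor, keeping variables with
   any level at p < 0.05.
5. **Confounder selection**: per candidate gene, nested backward
   conditional-independence elimination to a minimal outcome-predictive set
   V and its exposure-linked subset W (the adjustment set).
6. **Targeted estimation (the core)**: TMLE of, for exposure G = high
   expression of gene *j* and adjustment set W,

   - average effect `AE = E[Y(1) − Y(0)]`,
   - individual effects `IE_i = Q*(1, W_i) − Q*(0, W_i)`,
   - marginal odds ratio
     `MOR = E[Y(1)](1 − E[Y(0)]) / ((1 − E[Y(1)]) E[Y(0)])`,

   with initial `Q(G, W) = E[Y|G, W]` and `g(W) = P(G = 1|W)` from a Super
   Learner over five learners (glm, pairwise-interaction glm, elastic-net,
   gradient boosting, random forest), propensity truncation, a logistic
   fluctuation along the clever covariates `H1 = G/g`,
   `H0 = −(1−G)/(1−g)`, and influence-curve Wald inference (delta method on
   log MOR).
7. **Validation**: per-gene sensitivity/specificity and single/combined
   ROC AUC utilities for external cohorts.

A synthetic cohort generator with analytically known counterfactual truth
(`simulation_config()`, `generate_cohort()`, `enumerate_truth()`) underpins
the test suite: estimator bias, CI coverage, double robustness, and the
agreement of the confounder search with an exhaustive-subset oracle are all
measured against known ground truth.

## Worked example

A synthetic 300-sample, 800-gene cohort with one protective causal gene
(structural effect −1.2 on the mortality logit, i.e. true AE = −0.25,
true MOR = 0.33) whose expression is coupled to the latent immune/stromal
states, plus one binary and one continuous confounder:

```r
library(tmecausal)

cfg <- simulation_config(n_samples = 300, n_genes = 800, seed = 11,
                         latent_correlation = 0.8, latent_exposure_coef = 3.5,
                         gene_effect_logit = -1.2, causal_fold_change = 50)
coh <- generate_cohort(cfg)

res <- run_pipeline(pipeline_config(
  counts = coh$counts, clinical = coh$clinical, signatures = coh$signatures,
  out_dir = "demo_run", sl_library = "glm", v_folds = 5, seed = 5))

res$tmle[res$tmle$gene == "gene_0001", ]
#>        gene   MOR   p_MOR    AE AE_ci_low AE_ci_high    p_AE
#> 1 gene_0001 0.457 0.00138 -0.18    -0.288    -0.0725 0.00103
```

The pipeline recovers the causal gene from the expression matrix alone: it
passes both score-group DE contrasts, survives univariate screening, and
its targeted estimate AE = −0.18 (95% CI −0.29, −0.07) has the right sign
and magnitude (the residual gap to −0.25 comes from the median dichotomy
being a noisy readout of the structural exposure). A direct fit on the
structural exposure with both confounders adjusted is sharper:

```r
w <- coh$clinical[, c("advanced_disease", "age_std")]
tmle_estimate(coh$truth$outcome, coh$truth$exposure, w,
              q_learners = "glm", g_learners = "glm", seed = 1)
#> Targeted maximum likelihood fit (n = 300)
#>   AE  = -0.2034  (95% CI -0.3053, -0.1014)  p = 9.289e-05
#>   MOR = 0.4121  (95% CI 0.2614, 0.6496)  p = 0.0001347
#>   EY1 = 0.2713  EY0 = 0.4746  fluctuation iterations = 1
```

Every run directory contains per-stage TSV/JSON artifacts
(`scores.tsv`, `de_immune.tsv`, `degs_shared.tsv`, `screening.tsv`,
`covsel.json`, `tmle.tsv`) and a `manifest.json` with the seed, a
configuration hash, and per-stage record counts; reruns with the same
configuration and seed are byte-identical, and each `stage_*()` function
can be run standalone on the previous stage's artifacts.

## Documentation

The methods vignette (`vignettes/tme-biomarkers-methods.Rmd`) describes the
models, the estimator, the defaults and why they were chosen, what the
synthetic generator does and does not emulate, and known limitations.
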