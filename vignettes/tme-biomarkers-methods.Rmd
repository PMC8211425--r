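---
title: "Methods: targeted estimation of TME-related biomarker effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted estimation of TME-related biomarker effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`tmecausal` implements a discovery pipeline for tumor-microenvironment (TME)
related prognostic biomarkers in bulk tumor RNA-seq cohorts with a binary
mortality endpoint, of the kind assembled from TCGA ovarian serous cancer
data. The flow is:

1. **Cohort construction** — join expression and clinical tables, keep
   primary tumors, define 3-year mortality.
2. **TME scoring** — single-sample rank-based enrichment of immune and
   stromal signatures per sample; median split into high/low score groups.
3. **Differential expression** — negative-binomial Wald tests between the
   high and low groups of each score; direction-concordant intersection of
   the two DEG lists.
4. **Univariate screening** — logistic regression of mortality on each
   median-dichotomized DEG and each clinical factor.
5. **Confounder-set selection** — per candidate gene, a nested
   conditional-independence reduction of the covariate pool to a minimal
   adjustment set.
6. **Targeted estimation** — targeted maximum likelihood estimation (TMLE)
   of the average effect (AE), per-sample individual effects (IE), and the
   marginal odds ratio (MOR) of high expression on mortality, with Super
   Learner nuisance estimation and influence-curve inference.
7. **Validation utilities** — per-gene sensitivity/specificity and
   multi-gene ROC/AUC for external cohorts.

Every stage is exercised against a synthetic cohort generator whose
counterfactual ground truth is analytically known, so the estimator can be
audited without any external download.

# Outcome definition

The binary endpoint is death before a follow-up horizon (default 3 years):
Y = 1 for patients who died with overall survival time below the horizon,
Y = 0 for patients whose survival time reaches the horizon — including
patients who died later, since the horizon, not the final vital status,
defines the outcome. Patients alive with follow-up shorter than the horizon
carry no outcome information at the horizon and are excluded, itemized with
reasons. Times may be supplied in days (TCGA convention) or years.

# TME scoring

For one sample, genes are ranked by expression and walked in decreasing
order; the in-set cumulative curve climbs by `rank^tau` (normalized within
the set, `tau = 0.25` by default) and the out-of-set empirical CDF by
`1/(N - m)`. The score is the summed difference of the two curves —
positive when signature genes concentrate among the most expressed genes.
Counts are normalized to `log2(CPM + 1)` before ranking; because only ranks
enter, any strictly monotone normalization gives the same score, and the
documented default matters only for reproducibility. The combined score is
exactly the sum of the immune and stromal scores, echoing the
ESTIMATE-style construction in which the combined score tracks (inversely)
tumor purity; the purity mapping itself is not used downstream and is
omitted.

Note one numerical subtlety: with `tau = 0` (plain ECDF difference) the
score is exactly antisymmetric when a set placement is mirrored from the
top to the bottom of the ranking; with the default rank-magnitude weighting
the mirrored scores agree only to a few percent, because the in-set climb
depends mildly on the absolute ranks occupied.

Samples are split at the median score; values strictly above the median are
"high". The same tie rule is used when dichotomizing gene expression, so a
tied median mass always lands in the low group, and a constant vector is an
error rather than an arbitrary split.

# Differential expression

Between high and low score groups the package fits, per gene, a
negative-binomial generalized linear model with log link, a group
coefficient, and log size-factor offsets, where size factors are
median-of-ratios. The NB is parameterized by mean and dispersion
`alpha` with `Var = mu + alpha * mu^2`, the standard RNA-seq DE
parameterization. Dispersion is estimated per gene by method of moments on
normalized counts and shrunk toward a fitted `a0 + a1/mu` trend with a
configurable weight (default 0.5). This captures the qualitative behavior
of empirical-Bayes DE engines without reproducing any particular one;
equality with a specific engine is deliberately not claimed, though a
cross-check in the test suite shows fold-change estimates correlate > 0.98
with DESeq2 on simulated data.

Genes in which every count is below half the sample count are removed
before testing. That low-count rule is one reading of an ambiguous filter
convention; two alternatives ("total below n/2", "below n/2 in a majority
of samples") are provided as config options.

DEGs require `|log2FC| > 1.5` (fold change beyond 2^1.5; the threshold is
interpreted on the log2 scale) and Benjamini–Hochberg FDR < 0.05. The
shared list keeps genes up-regulated in both score contrasts or
down-regulated in both; discordant genes are dropped.

# Univariate screening

Each shared DEG is dichotomized at its median expression and regressed
against the outcome by univariate logistic regression; clinical factors are
regressed as-is with reference-coded levels. A variable survives when any
of its levels has p < 0.05 — so a categorical factor with one significant
stratum (for example, a single residual-disease category) is retained as a
whole. Separation is reported through a flag rather than an error.

The per-level odds ratios use Wald intervals `exp(coef ± 1.96·SE)`; for a
binary predictor this reproduces the contingency cross-product ratio to
numerical precision, which is how the published residual-disease rows are
reproduced in the test suite from the cohort's category counts alone.

# Minimal confounder sets

For gene `G_j`, the candidate pool `C` is all other candidate genes'
exposure indicators plus the screened clinical covariates. Two nested
backward-elimination reductions are run:

* **V**: repeatedly drop from `C` the covariate whose conditional
  independence test with the outcome, given the remaining set, has the
  largest p-value above the threshold (default 0.10); stop when every
  remaining covariate tests dependent. Empirically, the outcome is then
  conditionally independent of the discarded covariates given V.
* **W**: the same reduction of V against the exposure. W ⊆ V by
  construction and is the adjustment set passed to TMLE; V is reported for
  diagnostics.

The conditional-independence engine is pluggable. The default is a
likelihood-ratio test: for fully discrete candidate/conditioning columns it
is the stratified G² test (the canonical discrete conditional-independence
test of constraint-based structure learning); otherwise it compares
logistic regressions with and without the candidate. A permutation variant
(`engine = "perm"`) replaces the chi-square reference with a permutation
distribution when the analyst prefers a reference-free test. The G² default
was chosen after observing that any two structurally different test
statistics disagree on exactly-null covariates near the threshold at a rate
(roughly `2·threshold·(1 - rank correlation)` per null covariate) that
makes greedy selection needlessly unstable relative to exhaustive subset
search; with a shared test primitive, the check of greedy backward
elimination against brute-force smallest-subset search is a pure test of
the search strategy, and agreement exceeds 90% on four-covariate DAG
families at n = 5,000.

Ties in elimination order are broken by largest p-value then lexicographic
name, so selection is deterministic.

# Targeted maximum likelihood estimation

For binary exposure G (high expression), outcome Y, and adjustment set W,
the estimands are the average effect `AE = E[Y(1) - Y(0)]`, individual
effects `IE_i = Q(1, W_i) - Q(0, W_i)`, and the marginal odds ratio
`MOR = [E Y(1) (1 - E Y(0))] / [(1 - E Y(1)) E Y(0)]`, identified under
no-unmeasured-confounding and positivity (`0 < P(G=1|W) < 1`).

The estimator:

1. Initial outcome regression `Q(G, W)` and propensity `g(W)` by a Super
   Learner over five candidate learners — main-terms logistic, all-pairwise
   interaction logistic, elastic-net logistic (`alpha = 0.5`, lambda by
   internal 5-fold CV), gradient-boosted trees (100 rounds, depth 3,
   learning rate 0.1), and random forest (500 trees) — with 10-fold
   stratified CV and convex weights minimizing the cross-validated negative
   log-likelihood. Hyperparameters are documented defaults with a config
   override; the learner families, not settings, are the defining choice.
   A failing learner is excluded with weight zero, never a crash, and a
   single-learner library bypasses the CV layer entirely.
2. `g` truncated to `[0.025, 0.975]` (configurable); truncation touching
   more than a configurable fraction of samples raises a positivity
   warning, and a single-arm exposure is an error since the effect is then
   unidentifiable.
3. A logistic fluctuation with the two clever covariates `H1 = G/g(W)` and
   `H0 = -(1-G)/(1-g(W))` and offset `logit Q`, iterated (usually once, up
   to 10 times) until the empirical mean of the efficient influence curve
   falls below 1e-11 — so both arms' score equations are solved and
   `AE = mean(IE) = EY1 - EY0` holds to machine precision on every fit.
   The iteration count is exposed in the fit diagnostics.
4. Influence-curve standard errors and Wald intervals for AE; the MOR
   interval and p-value by the delta method on `log MOR`, matching the
   reporting convention of separate p-values for AE and MOR. IE is reported
   from the targeted regression, since the targeted fit is the final
   estimator.

Per-gene batch runs derive each gene's seed from the global seed and the
gene id, so results are invariant to candidate ordering, and one gene's
failure is recorded without aborting the batch.

# The synthetic cohort generator

The generator emulates what the analysis assumes about real cohorts, with
every structural parameter surfaced in `simulation_config()`:

* **Counts**: NB draws with per-gene base means `2^U(3, 9)` and dispersion
  0.2; immune and stromal signature genes (50 each by default) are elevated
  `signature_fold_change`-fold (default 4) in samples whose latent
  immune/stromal state is high. The two latent states are Bernoulli(1/2),
  optionally correlated (`latent_correlation`), since immune and stromal
  infiltration co-vary in real tumors — that correlation is what makes a
  direction-concordant shared DEG list non-empty.
* **Confounding**: by default one binary covariate (advanced disease,
  prevalence 0.5) and one standardized continuous covariate (age), each
  with logit coefficients +0.8 / +0.5 on both exposure and outcome — the
  positive-confounding pattern that biases crude comparisons toward the
  null for a protective exposure.
* **Exposure and outcome**: a structural binary exposure G (high expression
  of the designated causal gene) drawn from a logistic model on the
  confounders (optionally also on the latent TME states, which then act as
  instruments with no outcome path); outcome from a logistic structural
  model with `gene_effect_logit` (default -0.7) and a baseline 3-year
  mortality of 40%, matching the scale of the motivating cohort (a marginal
  risk difference near -0.15). The causal gene's counts are elevated
  `causal_fold_change`-fold under G = 1, so its median dichotomy is a
  noisy but faithful readout of G.
* **Truth**: per-sample counterfactual risks from the structural model give
  `true_IE`, `true_AE = mean(true_IE)` (exact by construction), and
  `true_MOR`. `enumerate_truth()` integrates the same quantities
  analytically over the confounder distribution when all confounders are
  discrete; it depends only on parameters, never the seed.

What the generator does **not** emulate: read-level sequencing noise,
batch effects, library-preparation artifacts, survival times beyond the
binary horizon outcome, gene–gene co-expression beyond the two latent
states, and measurement error in clinical covariates. Passing tests
therefore demonstrate correctness of the statistical machinery under the
assumed data-generating structure, not robustness to the full messiness of
real cohorts.

# Numerical choices and edge cases

* Probabilities are clipped to `(1e-6, 1 - 1e-6)` before any logit.
* The median-split tie rule (strictly greater = high) applies uniformly;
  constant vectors are an error.
* Constant covariate columns are auto-dropped from confounder selection
  with a logged step.
* In the NB Wald test, genes whose GLM fails to converge report `NA`
  p-values and are excluded from the BH adjustment.
* Super Learner weights are optimized on a softmax parameterization with a
  BFGS search; with one retained learner the weight is exactly 1.
* Seeds: a single global seed is mixed with a stage or gene label through a
  31-bit multiplicative hash (`derive_seed`), keeping every derived seed a
  valid 32-bit R seed and making batch order irrelevant.

# Problem sizes used in the shipped checks

The repeated-sampling checks run at sizes chosen to give tight Monte-Carlo
error while keeping the default suite quick on one core: 200 replicates at
n = 500 for estimator bias and CI coverage (with the correctly specified
single-learner library, which isolates estimator behavior from ensemble
variance), 10 replicates at n = 10,000 for double robustness, 2,000 null
genes at 50 + 50 samples for FDR calibration, and 50 replicates of the
four-covariate DAG family at n = 5,000 for the confounder-selection
agreement bound. The end-to-end pipeline demonstration uses 300 samples by
800 genes with a strongly TME-coupled causal gene (50-fold expression
elevation under exposure, exposure logit coupled to both latent states) so
the full screen-and-estimate path has unambiguous signal to recover.

# Known limitations

* The dispersion shrinkage is a deliberately simple stand-in for
  empirical-Bayes machinery; outlier handling (Cook's distance), apeglm
  shrinkage, and independent filtering are out of scope.
* Effects are defined for a median-dichotomized exposure; continuous,
  longitudinal, cross-validated, and survival-outcome TMLE variants are out
  of scope.
* The combined validation score is an in-sample logistic linear predictor —
  one documented fusion rule among many; its AUC is optimistic relative to
  held-out evaluation.
* Confounder-set selection inherits the finite-sample instability of any
  threshold-based conditional-independence search; the V/W sets should be
  read as data-driven suggestions, with the elimination logs reported for
  audit.
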