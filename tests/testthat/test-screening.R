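test_that("expression dichotomy uses the strictly-greater-than-median rule", {
  expect_identical(unname(dichotomize_expression(c(a = 1, b = 2, c = 3, d = 4))),
                   c(0L, 0L, 1L, 1L))
  expect_identical(unname(dichotomize_expression(c(a = 7, b = 7, c = 7, d = 9))),
                   c(0L, 0L, 0L, 1L))
  x <- c(a = 0.3, b = 2.5, c = 1.1, d = 9, e = 4)
  expect_identical(dichotomize_expression(x), dichotomize_expression(exp(x)))
  expect_error(dichotomize_expression(c(a = 2, b = 2)), "identical")
})

test_that("logistic OR equals the cross-product ratio for any 2x2 table", {
  set.seed(21)
  for (i in 1:8) {
    tab <- matrix(sample(5:40, 4), 2)  # a b / c d with y in rows
    x <- rep(c(1, 0, 1, 0), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
    y <- rep(c(1, 1, 0, 0), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
    r <- logistic_univariate(x, y)
    cross <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    expect_equal(r$odds_ratio, cross, tolerance = 1e-6)
  }
})

test_that("a predictor independent of the outcome has OR 1", {
  x <- rep(c(1, 0, 1, 0), c(30, 30, 20, 20))
  y <- rep(c(1, 1, 0, 0), c(30, 30, 20, 20))
  r <- logistic_univariate(x, y)
  expect_equal(r$odds_ratio, 1, tolerance = 1e-8)
})

test_that("published residual-disease associations reproduce from the count table", {
  d <- expand_count_table(osc_residual_disease_counts())
  r <- logistic_univariate(d$x, d$y, "Tumor residual disease")
  ## reported: 1.53 (0.70; 3.34); 1.64 (0.53; 5.10); 3.14 (1.31; 7.54)
  expect_equal(round(r$odds_ratio[r$level == "1-10 mm"], 2), 1.53)
  expect_equal(round(unlist(r[r$level == "1-10 mm", c("ci_low", "ci_high")]),
                     2), c(ci_low = 0.70, ci_high = 3.34))
  expect_equal(round(r$odds_ratio[r$level == "11-20 mm"], 2), 1.64)
  expect_equal(round(unlist(r[r$level == "11-20 mm", c("ci_low", "ci_high")]),
                     2), c(ci_low = 0.53, ci_high = 5.10))
  expect_equal(round(r$odds_ratio[r$level == ">20 mm"], 2), 3.14)
  expect_equal(round(unlist(r[r$level == ">20 mm", c("ci_low", "ci_high")]),
                     2), c(ci_low = 1.31, ci_high = 7.54))
  expect_equal(round(r$p_value[r$level == ">20 mm"], 3), 0.010)
})

test_that("separation is flagged, not fatal", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- c(rep(0, 10), rep(1, 10))
  r <- logistic_univariate(x, y)
  expect_true(r$separation)
})

test_that("screening keeps variables with any significant level", {
  set.seed(22)
  n <- 240
  ## one truly associated gene among nulls + a 3-level factor with one
  ## strong level
  y <- rbinom(n, 1, 0.45)
  cts <- simulate_count_matrix(2^runif(12, 5, 8), n_samples = n,
                               dispersion = 0.2)
  ## overwrite gene 1 so its high/low split tracks y strongly
  hi <- y == 1 | runif(n) < 0.15
  cts[1, ] <- as.integer(round(2^(6 + 2 * hi) + rpois(n, 3)))
  lev <- sample(c("ref", "mid", "bad"), n, TRUE)
  ## make 'bad' associated
  y[lev == "bad"] <- rbinom(sum(lev == "bad"), 1, 0.8)
  clinical <- data.frame(sample_id = colnames(cts),
                         grade = factor(lev, levels = c("ref", "mid", "bad")))
  scr <- screen_candidates(rownames(cts), cts, clinical, "grade",
                           setNames(y, colnames(cts)), alpha = 0.05)
  expect_true("gene_0001" %in% scr$candidate_genes)
  expect_true("grade" %in% scr$candidate_clinical)
  expect_identical(rownames(scr$exposures), colnames(cts))
})

test_that("a truly associated gene is retained with high power", {
  ## 50 null genes + 1 exposure gene. The exposure-only covariates leave the
  ## marginal (crude) association equal to the structural one, which is what
  ## the univariate screen estimates; confounded configurations attenuate it
  ## and are the business of the targeted-estimation stage instead.
  confs <- list(list(name = "z", dist = "binary", p = 0.5,
                     coef_exposure = 0.8, coef_outcome = 0))
  hits <- 0; reps <- 25
  for (r in seq_len(reps)) {
    coh <- generate_cohort(simulation_config(
      n_samples = 400, n_genes = 51, n_signature_genes = 0,
      confounders = confs,
      gene_effect_logit = -1.2, causal_fold_change = 8, seed = 100 + r))
    scr <- screen_candidates(rownames(coh$counts), coh$counts,
                             clinical = NULL, character(),
                             coh$truth$outcome, alpha = 0.05)
    hits <- hits + ("gene_0001" %in% scr$candidate_genes)
  }
  expect_gt(hits / reps, 0.8)
})
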