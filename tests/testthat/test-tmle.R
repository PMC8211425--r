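test_that("marginal odds ratio evaluates its formula and symmetry", {
  expect_equal(marginal_odds_ratio(0.3, 0.3), 1, tolerance = 1e-14)
  expect_equal(marginal_odds_ratio(0.5, 0.25), 3, tolerance = 1e-14)
  set.seed(51)
  for (i in 1:10) {
    a <- runif(1, 0.05, 0.95); b <- runif(1, 0.05, 0.95)
    expect_equal(marginal_odds_ratio(a, b) * marginal_odds_ratio(b, a), 1,
                 tolerance = 1e-12)
  }
  expect_error(marginal_odds_ratio(0, 0.5), "strictly inside")
  expect_error(marginal_odds_ratio(0.5, 1), "strictly inside")
})

test_that("randomized null exposure gives estimates near zero effect", {
  set.seed(52)
  n <- 5000
  w <- data.frame(z = rnorm(n))
  g <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, 0.4)
  fit <- tmle_estimate(y, g, w, q_learners = "glm", g_learners = "glm",
                       seed = 1)
  expect_lt(abs(fit$AE), 2 * fit$se_AE)
  expect_true(fit$ci_MOR[1] < 1 && 1 < fit$ci_MOR[2])
})

test_that("plug-in identities hold to machine precision on every fit", {
  set.seed(53)
  for (r in 1:5) {
    coh <- default_cohort(n = 300, seed = 500 + r)
    w <- coh$clinical[, c("advanced_disease", "age_std")]
    fit <- tmle_estimate(coh$truth$outcome, coh$truth$exposure, w,
                         q_learners = "glm", g_learners = "glm", seed = r)
    expect_equal(fit$AE, mean(fit$IE), tolerance = 1e-12)
    expect_equal(fit$AE, fit$EY1 - fit$EY0, tolerance = 1e-12)
    expect_equal(fit$MOR,
                 (fit$EY1 * (1 - fit$EY0)) / ((1 - fit$EY1) * fit$EY0),
                 tolerance = 1e-12)
    expect_lte(abs(fit$eic_mean), 1e-8)
  }
})

test_that("with saturated Q and known g, TMLE equals nonparametric g-computation", {
  set.seed(54)
  n <- 4000
  z <- rbinom(n, 1, 0.4)
  g_true <- plogis(-0.5 + 1.2 * z)
  g <- rbinom(n, 1, g_true)
  y <- rbinom(n, 1, plogis(-0.8 + 0.9 * z - 0.7 * g))
  ## saturated outcome model over the 4 (g, z) cells
  q0 <- ave(y, z, g, FUN = mean)
  qq <- cbind(
    Q0 = vapply(seq_len(n), function(i) mean(y[g == 0 & z == z[i]]), 0),
    Q1 = vapply(seq_len(n), function(i) mean(y[g == 1 & z == z[i]]), 0))
  fit <- tmle_estimate(y, g, data.frame(z = z), q_init = qq, g_init = g_true)
  expect_equal(fit$AE, gcomp_strata(y, g, z), tolerance = 1e-4)
  expect_lte(abs(fit$eic_mean), 1e-8)
})

test_that("double robustness: one correct nuisance model suffices", {
  set.seed(55)
  n <- 10000
  reps <- 8
  bias_qmiss <- numeric(reps); bias_gmiss <- numeric(reps); truth <- numeric(reps)
  for (r in seq_len(reps)) {
    z <- rbinom(n, 1, 0.5)
    g_true <- plogis(-0.4 + 1.1 * z)
    g <- rbinom(n, 1, g_true)
    p1 <- plogis(-0.6 + 1.0 * z - 0.8)
    p0 <- plogis(-0.6 + 1.0 * z)
    y <- rbinom(n, 1, ifelse(g == 1, p1, p0))
    truth[r] <- mean(p1 - p0)
    w <- data.frame(z = z)
    ## intercept-only Q, correct g
    f1 <- tmle_estimate(y, g, w, q_learners = "mean", g_learners = "glm",
                        seed = r)
    ## correct Q, intercept-only g
    f2 <- tmle_estimate(y, g, w, q_learners = "glm", g_learners = "mean",
                        seed = r)
    bias_qmiss[r] <- f1$AE - truth[r]
    bias_gmiss[r] <- f2$AE - truth[r]
  }
  mc_se <- function(x) sd(x) / sqrt(length(x))
  expect_lt(abs(mean(bias_qmiss)), 3 * mc_se(bias_qmiss))
  expect_lt(abs(mean(bias_gmiss)), 3 * mc_se(bias_gmiss))
})

test_that("positivity problems raise errors or warnings as appropriate", {
  set.seed(56)
  y <- rbinom(100, 1, 0.5)
  expect_error(tmle_estimate(y, rep(1L, 100), data.frame(z = rnorm(100))),
               "positivity")
  ## heavy truncation triggers the warning artifact
  z <- rnorm(500)
  g <- rbinom(500, 1, plogis(6 * z))
  y <- rbinom(500, 1, 0.4)
  expect_warning(
    tmle_estimate(y, g, data.frame(z = z), q_learners = "glm",
                  g_learners = "glm", seed = 1,
                  positivity_warn_frac = 0.05),
    "positivity")
})

test_that("per-gene batch is order-invariant and fault-tolerant", {
  set.seed(57)
  coh <- default_cohort(n = 400, seed = 60)
  expr <- log2_cpm(coh$counts)
  genes <- c("gene_0001", "gene_0002", "gene_0003")
  expo <- sapply(genes, function(g) dichotomize_expression(expr[g, ]))
  covd <- coh$clinical[, c("advanced_disease", "age_std")]
  sets <- list(gene_0001 = c("advanced_disease", "age_std"),
               gene_0002 = "age_std",
               gene_0003 = character())
  y <- coh$truth$outcome
  r1 <- run_per_gene(genes, expo, covd, y, sets, seed = 9,
                     q_learners = "glm", g_learners = "glm")
  r2 <- run_per_gene(rev(genes), expo, covd, y, sets, seed = 9,
                     q_learners = "glm", g_learners = "glm")
  for (g in genes) {
    expect_equal(r1$table[r1$table$gene == g, ]$AE,
                 r2$table[r2$table$gene == g, ]$AE, tolerance = 1e-12)
  }
  ## empty candidate list gives an empty, well-formed table
  r0 <- run_per_gene(character(), expo, covd, y, sets, seed = 9)
  expect_identical(nrow(r0$table), 0L)
  ## a failing gene is recorded without aborting the batch
  expo_bad <- expo; expo_bad[, "gene_0002"] <- 1L
  rb <- run_per_gene(genes, expo_bad, covd, y, sets, seed = 9,
                     q_learners = "glm", g_learners = "glm")
  expect_false(is.na(rb$table$error[rb$table$gene == "gene_0002"]))
  expect_true(is.na(rb$table$error[rb$table$gene == "gene_0001"]))
})

test_that("a causal gene is detected and a null gene is not", {
  coh <- generate_cohort(simulation_config(
    n_samples = 800, n_genes = 20, n_signature_genes = 0,
    gene_effect_logit = -1.2, causal_fold_change = 8, seed = 61))
  expr <- log2_cpm(coh$counts)
  genes <- c("gene_0001", "gene_0010")   # causal, null
  expo <- sapply(genes, function(g) dichotomize_expression(expr[g, ]))
  covd <- coh$clinical[, c("advanced_disease", "age_std")]
  sets <- list(gene_0001 = names(covd), gene_0010 = names(covd))
  res <- run_per_gene(genes, expo, covd, coh$truth$outcome, sets, seed = 3,
                      q_learners = "glm", g_learners = "glm")
  causal <- res$table[res$table$gene == "gene_0001", ]
  null <- res$table[res$table$gene == "gene_0010", ]
  expect_lt(causal$AE_ci_high, 0)      # negative effect, CI excludes zero
  expect_true(null$AE_ci_low < 0 && null$AE_ci_high > 0)
})
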