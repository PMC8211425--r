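test_that("sensitivity and specificity follow the confusion matrix", {
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(sensitivity_specificity(labels, labels),
               c(sensitivity = 1, specificity = 1))
  expect_equal(sensitivity_specificity(1 - labels, labels),
               c(sensitivity = 0, specificity = 0))
  ## TP=3 FN=1 TN=4 FP=2
  pred <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  ss <- sensitivity_specificity(pred, labels)
  expect_equal(unname(ss), c(3 / 4, 4 / 6), tolerance = 1e-12)
  expect_error(sensitivity_specificity(pred, rep(1, 10)), "both label")
})

test_that("AUC equals the all-pairs Mann-Whitney statistic exactly", {
  set.seed(71)
  for (r in 1:20) {
    n <- sample(10:40, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    score <- sample(round(rnorm(n), 1))  # rounded to force ties
    expect_identical(roc_auc(score, labels), auc_pairs(score, labels))
  }
})

test_that("AUC basics: separation, invariance, complement symmetry", {
  labels <- rep(0:1, each = 20)
  score <- c(rnorm(20, 0), rnorm(20, 10))
  expect_equal(roc_auc(score, labels), 1)
  ## monotone transform invariance
  expect_equal(roc_auc(exp(score / 10), labels), 1)
  set.seed(72)
  s <- rnorm(40)
  expect_equal(roc_auc(s, labels), roc_auc(2 * s + 5, labels),
               tolerance = 1e-12)
  expect_equal(roc_auc(s, labels) + roc_auc(-s, labels), 1,
               tolerance = 1e-12)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(73)
  labels <- rbinom(60, 1, 0.4)
  score <- rnorm(60) + labels
  ref <- as.numeric(pROC::auc(pROC::roc(labels, score, quiet = TRUE)))
  expect_equal(roc_auc(score, labels), ref, tolerance = 1e-12)
})

test_that("noisy binary score approaches its closed-form AUC", {
  ## score = label with a fraction eps flipped: AUC -> (1-eps)... computed
  ## from the tie-aware Mann-Whitney form
  set.seed(74)
  n <- 20000; eps <- 0.25
  labels <- rbinom(n, 1, 0.5)
  flip <- runif(n) < eps
  score <- ifelse(flip, 1 - labels, labels)
  ## closed form: P(s1 > s0) + 0.5 P(tie) with s1~Bern(1-eps), s0~Bern(eps)
  expected <- (1 - eps) * (1 - eps) +
    0.5 * ((1 - eps) * eps + eps * (1 - eps) +
             (1 - eps) * eps + eps * (1 - eps) -
             ((1 - eps) * eps + eps * (1 - eps)))
  ## simplify: P(s1=1)P(s0=0) + 0.5 [P(s1=1)P(s0=1) + P(s1=0)P(s0=0)]
  expected <- (1 - eps)^2 + 0.5 * ((1 - eps) * eps + eps * (1 - eps))
  expect_equal(roc_auc(score, labels), expected, tolerance = 0.02)
})

test_that("combined score reduces to the single gene for k = 1", {
  set.seed(75)
  expr <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "g1"))
  labels <- rbinom(100, 1, plogis(expr[, 1]))
  comb <- combine_genes(expr, labels)
  expect_equal(comb$auc, roc_auc(dichotomize_expression(expr[, 1]), labels),
               tolerance = 1e-12)
})

test_that("adding a noise gene never lowers in-sample combined AUC", {
  set.seed(76)
  n <- 300
  expr <- cbind(g1 = rnorm(n), g2 = rnorm(n))
  labels <- rbinom(n, 1, plogis(1.5 * dichotomize_expression(expr[, "g1"]) - 0.7))
  a2 <- combine_genes(expr, labels)$auc
  expr3 <- cbind(expr, noise = rnorm(n))
  a3 <- combine_genes(expr3, labels)$auc
  expect_gte(a3, a2 - 1e-12)
})

test_that("a 4-gene signature outperforms its best single gene in-sample", {
  set.seed(77)
  n <- 500
  expr <- matrix(rnorm(4 * n), n, 4,
                 dimnames = list(NULL, paste0("g", 1:4)))
  gx <- apply(expr, 2, function(e) as.numeric(dichotomize_expression(e)))
  labels <- rbinom(n, 1, plogis(-0.5 + 0.8 * gx[, 1] + 0.6 * gx[, 2] +
                                  0.5 * gx[, 3] - 0.6 * gx[, 4]))
  rep <- validation_report(expr, labels)
  expect_gte(rep$combined$auc, max(rep$per_gene$auc))
  expect_true(all(rep$per_gene$sensitivity >= 0 & rep$per_gene$sensitivity <= 1))
  expect_true(rep$combined$sensitivity + rep$combined$specificity > 1)
})

test_that("gene aliases substitute for unmeasured genes in validation", {
  set.seed(78)
  expr <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("CROCC", "g2")))
  labels <- rbinom(100, 1, 0.5)
  rep <- validation_report(expr, labels, alias_map = c(CROCC2 = "CROCC"))
  expect_true("CROCC2" %in% rep$per_gene$gene)
})
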