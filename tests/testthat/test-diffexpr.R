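test_that("low-count filter applies the all-samples-below rule", {
  cts <- rbind(all4 = rep(4L, 10),
               spike = c(100L, rep(0L, 9)),
               edge = rep(5L, 10))
  expect_identical(rownames(filter_low_counts(cts)), c("spike", "edge"))
  ## brute-force re-application on a random toy matrix
  set.seed(11)
  m <- matrix(rpois(300, 4), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  kept <- filter_low_counts(m)
  manual <- m[!apply(m, 1, function(x) all(x < 5)), ]
  expect_identical(kept, manual)
})

test_that("alternative filter readings are available", {
  ## n = 4 samples, so the threshold is 2
  cts <- rbind(a = c(1L, 1L, 1L, 1L),   # every count below 2, total 4
               b = c(9L, 0L, 0L, 0L),   # one large count, 3/4 below 2
               c = c(0L, 0L, 0L, 1L))   # everything tiny, total 1
  expect_identical(rownames(filter_low_counts(cts, "all_below")), "b")
  expect_identical(rownames(filter_low_counts(cts, "total_below")), c("a", "b"))
  expect_identical(nrow(filter_low_counts(cts, "majority_below")), 0L)
})

test_that("size factors recover proportionality constants", {
  set.seed(3)
  base <- rpois(200, 50) + 1L
  k <- c(0.5, 1, 2, 4)
  cts <- sapply(k, function(f) as.integer(round(base * f)))
  rownames(cts) <- paste0("g", 1:200)
  sf <- size_factors(cts)
  ## equal to k up to geometric-mean normalization
  expect_equal(unname(sf / exp(mean(log(sf)))),
               k / exp(mean(log(k))), tolerance = 0.02)
})

test_that("identical columns in two groups give log2 fold change zero", {
  set.seed(4)
  col <- rpois(50, 30) + 10L
  cts <- cbind(a = col, b = col)
  rownames(cts) <- paste0("g", 1:50)
  grp <- factor(c("low", "high"), levels = c("low", "high"))
  res <- nb_wald_test(cts, grp)
  expect_equal(res$log2_fc, rep(0, 50), tolerance = 1e-8)
})

test_that("a 4-fold change is recovered and nulls stay calibrated", {
  set.seed(5)
  mu <- 2^runif(400, 4, 9)
  grp <- factor(rep(c("low", "high"), each = 50), levels = c("low", "high"))
  fold <- matrix(1, 400, 100)
  fold[1, grp == "high"] <- 4
  cts <- simulate_count_matrix(mu, fold, dispersion = 0.1)
  res <- nb_wald_test(cts, grp)
  expect_lt(abs(res$log2_fc[1] - 2), 0.3)
  expect_lt(res$fdr[1], 0.01)
  ## null genes: BH-adjusted discoveries stay near zero
  expect_lte(mean(res$fdr[-1] < 0.05, na.rm = TRUE), 0.05)
})

test_that("BH adjustment inside the pipeline matches the brute-force step-up", {
  set.seed(6)
  for (i in 1:5) {
    p <- runif(sample(5:20, 1))
    expect_equal(p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  }
  ## and the fdr column is the BH adjustment of the p column
  mu <- 2^runif(50, 4, 8)
  cts <- simulate_count_matrix(mu, n_samples = 20, dispersion = 0.2)
  grp <- split_by_median(seq_len(20))
  res <- nb_wald_test(cts, grp)
  expect_equal(res$fdr, bh_brute(res$p_value), tolerance = 1e-12)
})

test_that("DEG selection applies both cutoffs with direction tags", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2_fc = c(1.6, 1.4, -2.0, 1.8),
                    p_value = c(.001, .0001, .01, .2),
                    fdr = c(0.01, 0.001, 0.04, 0.3),
                    direction = c("up", "up", "down", "up"))
  sel <- select_degs(res)
  expect_setequal(sel$gene, c("a", "c"))
  expect_identical(sel$direction[sel$gene == "c"], "down")
})

test_that("shared DEGs keep only direction-concordant genes", {
  imm <- data.frame(gene = c("u1", "u2", "d1", "x"),
                    direction = c("up", "up", "down", "up"))
  str <- data.frame(gene = c("u1", "d1", "x", "u3"),
                    direction = c("up", "down", "down", "up"))
  sh <- shared_degs(imm, str)
  expect_setequal(sh$gene, c("u1", "d1"))
  ## set-algebra oracle on random toy lists
  set.seed(7)
  for (i in 1:5) {
    g <- paste0("g", 1:15)
    imm <- data.frame(gene = sample(g, 8),
                      direction = sample(c("up", "down"), 8, TRUE))
    str <- data.frame(gene = sample(g, 8),
                      direction = sample(c("up", "down"), 8, TRUE))
    sh <- shared_degs(imm, str)
    oracle <- union(
      intersect(imm$gene[imm$direction == "up"], str$gene[str$direction == "up"]),
      intersect(imm$gene[imm$direction == "down"], str$gene[str$direction == "down"]))
    expect_setequal(sh$gene, oracle)
  }
})

test_that("group with empty level or all-zero library is rejected", {
  cts <- matrix(1L, 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expect_error(nb_wald_test(cts, factor(rep("low", 4), levels = c("low", "high"))),
               "non-empty")
})

test_that("fold-change estimates broadly agree with an established NB engine", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  mu <- 2^runif(150, 5, 9)
  grp <- factor(rep(c("low", "high"), each = 20), levels = c("low", "high"))
  fold <- matrix(1, 150, 40)
  fold[1:10, grp == "high"] <- rep(c(4, 0.25), each = 5)
  cts <- simulate_count_matrix(mu, fold, dispersion = 0.15)
  mine <- nb_wald_test(cts, grp)
  dds <- DESeq2::DESeqDataSetFromMatrix(cts, data.frame(grp = grp), ~grp)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  ref <- DESeq2::results(dds, contrast = c("grp", "high", "low"))
  expect_gt(cor(mine$log2_fc, ref$log2FoldChange, use = "complete.obs"), 0.98)
  expect_lt(mean(abs(mine$log2_fc[1:10] - ref$log2FoldChange[1:10])), 0.2)
})
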