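#' Remove genes with uniformly low counts
#'
#' Drops gene g when every one of its counts is below half the number of
#' samples (`count[g, s] < n/2` for all s). Alternative readings of the
#' low-count rule are available via `rule`: `"all_below"` (default, the
#' adopted reading), `"total_below"` (total count below n/2) or
#' `"majority_below"` (count below n/2 in more than half the samples).
#'
#' @param counts genes x samples count matrix, >= 2 samples.
#' @param rule which low-count reading to apply.
#' @return the filtered count matrix.
#' @export
filter_low_counts <- function(counts,
                              rule = c("all_below", "total_below",
                                       "majority_below")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(counts), ncol(counts) >= 2L)
  half <- ncol(counts) / 2
  drop <- switch(rule,
    all_below = apply(counts, 1, function(x) all(x < half)),
    total_below = rowSums(counts) < half,
    majority_below = apply(counts, 1, function(x) mean(x < half) > 0.5))
  counts[!drop, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over genes with
#' all-positive counts, of the ratio of a sample's count to the geometric
#' mean across samples.
#'
#' @param counts genes x samples count matrix.
#' @return named numeric vector of size factors (one per sample).
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts))
  lg <- log(counts)
  ref <- rowMeans(lg)                     # -Inf for genes with any zero
  usable <- is.finite(ref)
  if (!any(usable)) stop("no gene with all-positive counts; cannot form size factors")
  sf <- apply(lg[usable, , drop = FALSE], 2, function(x)
    exp(stats::median(x - ref[usable])))
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("degenerate size factors")
  sf
}

## per-gene NB dispersion: method-of-moments, shrunk toward a fitted
## mean-dispersion trend a0 + a1/mu
estimate_dispersions <- function(counts, groups, sf, shrink_weight = 0.5) {
  norm <- sweep(counts, 2, sf, "/")
  lv <- levels(groups)
  ## pooled within-group moments
  mu <- rowMeans(norm)
  resid_var <- rep(0, nrow(counts))
  for (g in lv) {
    sub <- norm[, groups == g, drop = FALSE]
    if (ncol(sub) >= 2L) {
      resid_var <- resid_var +
        apply(sub, 1, stats::var) * (ncol(sub) - 1L)
    }
  }
  df <- ncol(counts) - length(lv)
  v <- if (df > 0) resid_var / df else mu  # fall back to Poisson-scale
  raw <- pmax((v - mu) / mu^2, 1e-8)
  ## gamma-style trend on genes with informative estimates
  ok <- mu > 0 & raw > 1e-8
  if (sum(ok) >= 10L) {
    fit <- stats::lm(raw[ok] ~ I(1 / mu[ok]))
    a <- pmax(stats::coef(fit), 0)
    trend <- pmax(a[1] + a[2] / pmax(mu, 1e-8), 1e-8)
  } else {
    trend <- rep(stats::median(raw), length(raw))
  }
  alpha <- shrink_weight * trend + (1 - shrink_weight) * raw
  pmax(alpha, 1e-8)
}

#' Negative-binomial Wald test between two groups
#'
#' For each gene, fits a negative-binomial generalized linear model of
#' counts on the group label with log link and log size-factor offset. The
#' group coefficient (converted to the log2 scale) is the log2 fold change
#' of `high` versus `low`; its Wald statistic gives the p-value, and p-values
#' are Benjamini-Hochberg adjusted across tested genes. Gene-wise dispersions
#' are method-of-moments estimates shrunk toward a fitted mean-dispersion
#' trend (`Var = mu + alpha * mu^2`).
#'
#' @param counts filtered genes x samples count matrix.
#' @param groups factor with levels `c("low", "high")` over samples.
#' @param shrink_weight weight on the trend in the dispersion shrinkage
#'   (0 = raw gene-wise estimate, 1 = trend only).
#' @return data.frame: `gene`, `base_mean`, `log2_fc` (high vs low),
#'   `se_log2_fc`, `p_value`, `fdr`, `direction` (`"up"`/`"down"`).
#' @export
nb_wald_test <- function(counts, groups, shrink_weight = 0.5) {
  stopifnot(is.matrix(counts))
  groups <- factor(groups, levels = c("low", "high"))
  if (any(table(groups) == 0L)) stop("both groups must be non-empty")
  sf <- size_factors(counts)
  if (any(tapply(colSums(counts), groups, sum) == 0)) {
    stop("a group has all-zero library size")
  }
  alpha <- estimate_dispersions(counts, groups, sf, shrink_weight)
  off <- log(sf)
  x <- stats::model.matrix(~groups)
  res <- vapply(seq_len(nrow(counts)), function(i) {
    yi <- counts[i, ]
    fam <- MASS::negative.binomial(theta = 1 / alpha[i])
    fit <- tryCatch(
      stats::glm.fit(x, yi, family = fam, offset = off,
                     control = stats::glm.control(maxit = 50)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(c(NA_real_, NA_real_, NA_real_))
    b <- fit$coefficients[2]
    ## Wald SE from the weighted information matrix
    xw <- x * sqrt(fit$weights)
    xtx <- crossprod(xw)
    se <- tryCatch(sqrt(solve(xtx)[2, 2]), error = function(e) NA_real_)
    c(b, se, mean(yi / sf))
  }, numeric(3))
  b <- res[1, ]; se <- res[2, ]
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(counts),
             base_mean = res[3, ],
             log2_fc = b / log(2),
             se_log2_fc = se / log(2),
             p_value = p,
             fdr = fdr,
             direction = ifelse(b >= 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Select differentially expressed genes by fold-change and FDR cutoffs
#'
#' @param results data.frame from [nb_wald_test()].
#' @param lfc_cut keep genes with `|log2_fc| > lfc_cut` (default 1.5, i.e.
#'   fold change beyond 2^1.5).
#' @param fdr_cut keep genes with `fdr < fdr_cut` (default 0.05).
#' @return subset of `results` satisfying both cutoffs.
#' @export
select_degs <- function(results, lfc_cut = 1.5, fdr_cut = 0.05) {
  stopifnot(nrow(results) > 0)
  keep <- !is.na(results$fdr) &
    abs(results$log2_fc) > lfc_cut & results$fdr < fdr_cut
  results[keep, , drop = FALSE]
}

#' Direction-concordant intersection of two DEG lists
#'
#' Keeps genes that are up-regulated in both lists or down-regulated in
#' both lists; genes with discordant directions are dropped.
#'
#' @param immune_degs,stromal_degs data.frames with `gene` and `direction`.
#' @return data.frame: `gene`, `direction`.
#' @export
shared_degs <- function(immune_degs, stromal_degs) {
  up <- intersect(immune_degs$gene[immune_degs$direction == "up"],
                  stromal_degs$gene[stromal_degs$direction == "up"])
  dn <- intersect(immune_degs$gene[immune_degs$direction == "down"],
                  stromal_degs$gene[stromal_degs$direction == "down"])
  data.frame(gene = c(up, dn),
             direction = rep(c("up", "down"), c(length(up), length(dn))),
             stringsAsFactors = FALSE)
}
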