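# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own code paths.

## Benjamini-Hochberg by the textbook step-up definition
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## single-sample enrichment by explicit position-by-position summation
ssgsea_brute <- function(expression, set, exponent = 0.25) {
  r <- rank(expression, ties.method = "average")
  ord <- order(expression, decreasing = TRUE)
  genes <- names(expression)[ord]
  rr <- r[ord]
  inset <- genes %in% set
  denom_in <- sum(rr[inset]^exponent)
  n_out <- sum(!inset)
  p_in <- 0; p_out <- 0; es <- 0
  for (i in seq_along(genes)) {
    if (inset[i]) p_in <- p_in + rr[i]^exponent / denom_in
    else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  unname(es)
}

## AUC by comparing every positive-negative pair
auc_pairs <- function(score, labels) {
  pos <- score[labels == 1]; neg <- score[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

## nonparametric g-computation: stratum-weighted difference of arm means
gcomp_strata <- function(y, g, z) {
  strata <- split(seq_along(y), z)
  est <- 0
  for (idx in strata) {
    w <- length(idx) / length(y)
    est <- est + w * (mean(y[idx][g[idx] == 1]) - mean(y[idx][g[idx] == 0]))
  }
  est
}

## stratified G^2 test of x _||_ t | S (all columns binary)
g2_ci_test <- function(data, t, x, S) {
  key <- if (length(S)) interaction(data[S], drop = TRUE)
         else factor(rep(1, nrow(data)))
  stat <- 0; df <- 0
  for (lev in levels(key)) {
    idx <- key == lev
    tab <- table(factor(data[[x]][idx], levels = 0:1),
                 factor(t[idx], levels = 0:1))
    rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
    if (sum(rs > 0) < 2 || sum(cs > 0) < 2) next
    expd <- outer(rs, cs) / n
    nz <- tab > 0
    stat <- stat + 2 * sum(tab[nz] * log(tab[nz] / expd[nz]))
    df <- df + (sum(rs > 0) - 1) * (sum(cs > 0) - 1)
  }
  if (df == 0) return(1)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

## exhaustive search for the smallest S with t _||_ C\S | S under G^2 tests;
## ties broken by subset size then lexicographic membership
minimal_set_brute <- function(data, t, candidates, threshold = 0.1) {
  k <- length(candidates)
  subsets <- list()
  for (size in 0:k) {
    combs <- utils::combn(candidates, size, simplify = FALSE)
    ## lexicographic order within a size
    combs <- combs[order(vapply(combs, paste, "", collapse = ","))]
    for (S in combs) {
      rest <- setdiff(candidates, S)
      ok <- all(vapply(rest, function(x)
        g2_ci_test(data, t, x, S) > threshold, logical(1)))
      if (ok) return(sort(S))
    }
  }
  sort(candidates)
}

## the nested V -> W reduction under the brute-force search
covsel_brute <- function(data, y, g, candidates, threshold = 0.1) {
  V <- minimal_set_brute(data, y, candidates, threshold)
  W <- if (length(V)) minimal_set_brute(data, g, V, threshold) else character()
  list(V = V, W = W)
}

## toy DAG for confounder-set selection: Z1 confounds (when the exposure
## affects Y), Z2 is outcome-only, Z3 exposure-only, Z4 pure noise
simulate_covsel_dag <- function(n, beta_g_on_y = 0) {
  z1 <- rbinom(n, 1, 0.5); z2 <- rbinom(n, 1, 0.5)
  z3 <- rbinom(n, 1, 0.5); z4 <- rbinom(n, 1, 0.5)
  g <- rbinom(n, 1, plogis(-1.2 + 1.2 * z1 + 1.2 * z3))
  y <- rbinom(n, 1, plogis(-1.2 + 1.2 * z1 + 1.2 * z2 + beta_g_on_y * g))
  list(data = data.frame(z1 = z1, z2 = z2, z3 = z3, z4 = z4), g = g, y = y)
}

## small helper: cohort at the generator's default study conditions
default_cohort <- function(n = 500, seed = 1, ...) {
  generate_cohort(simulation_config(n_samples = n, n_genes = 50,
                                    n_signature_genes = 10, seed = seed, ...))
}
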