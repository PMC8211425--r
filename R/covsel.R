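#' Conditional-independence test of one covariate against a binary target
#'
#' Default engine `"lrt"`: a likelihood-ratio test of conditional
#' independence. When the candidate and every conditioning covariate are
#' discrete (factor, logical, or numeric with few unique values) this is the
#' stratified G-squared test — the likelihood-ratio chi-square of the
#' candidate-by-target table summed over the strata of the conditioning
#' set, the standard discrete conditional-independence test of
#' constraint-based structure learning. With continuous covariates it falls
#' back to comparing the logistic regression of the target on the
#' conditioning set with and without the candidate (chi-square reference on
#' the difference in residual degrees of freedom). Engine `"perm"` replaces
#' the chi-square reference of the regression form by a permutation
#' distribution of the statistic obtained by permuting the candidate's
#' values, a heavier but reference-free alternative.
#'
#' @param data data.frame holding the covariates.
#' @param target 0/1 vector (outcome or exposure).
#' @param candidate name of the column being tested.
#' @param conditioning character vector of conditioning column names.
#' @param engine `"lrt"` or `"perm"`.
#' @param n_perm permutations for the `"perm"` engine.
#' @return p-value for conditional dependence of target and candidate given
#'   the conditioning set.
#' @export
ci_test <- function(data, target, candidate, conditioning = character(),
                    engine = c("lrt", "perm"), n_perm = 200L) {
  engine <- match.arg(engine)
  stopifnot(candidate %in% names(data), all(target %in% 0:1))
  conditioning <- setdiff(conditioning, candidate)
  is_discrete <- function(v) {
    is.factor(v) || is.character(v) || is.logical(v) ||
      length(unique(v)) <= 5L
  }
  if (engine == "lrt" &&
      all(vapply(data[, c(candidate, conditioning), drop = FALSE],
                 is_discrete, logical(1)))) {
    return(g2_test(data, target, candidate, conditioning))
  }
  lrt_stat <- function(cand_values) {
    d <- data[, conditioning, drop = FALSE]
    d$..cand <- cand_values
    d$..y <- target
    f0 <- if (length(conditioning)) {
      stats::as.formula(paste("..y ~", paste(sprintf("`%s`", conditioning),
                                             collapse = " + ")))
    } else stats::as.formula("..y ~ 1")
    f1 <- stats::update(f0, . ~ . + ..cand)
    m0 <- suppressWarnings(stats::glm(f0, stats::binomial(), data = d))
    m1 <- suppressWarnings(stats::glm(f1, stats::binomial(), data = d))
    c(stat = m0$deviance - m1$deviance,
      df = m0$df.residual - m1$df.residual)
  }
  obs <- lrt_stat(data[[candidate]])
  if (obs[["df"]] <= 0) return(1)  # candidate adds nothing estimable
  if (engine == "lrt") {
    stats::pchisq(obs[["stat"]], df = obs[["df"]], lower.tail = FALSE)
  } else {
    null_stats <- replicate(n_perm,
      lrt_stat(sample(data[[candidate]]))[["stat"]])
    (1 + sum(null_stats >= obs[["stat"]])) / (n_perm + 1)
  }
}

## stratified G^2 (likelihood-ratio chi-square) conditional-independence
## test for discrete data: sum the 2xk table G^2 over conditioning strata
g2_test <- function(data, target, candidate, conditioning) {
  key <- if (length(conditioning)) {
    interaction(data[, conditioning, drop = FALSE], drop = TRUE)
  } else factor(rep(1L, nrow(data)))
  stat <- 0; df <- 0L
  for (lev in levels(key)) {
    idx <- key == lev
    tab <- table(data[[candidate]][idx], factor(target[idx], levels = 0:1))
    rs <- rowSums(tab); cs <- colSums(tab); tot <- sum(tab)
    if (sum(rs > 0) < 2L || sum(cs > 0) < 2L) next
    expd <- outer(rs, cs) / tot
    nz <- tab > 0
    stat <- stat + 2 * sum(tab[nz] * log(tab[nz] / expd[nz]))
    df <- df + (sum(rs > 0) - 1L) * (sum(cs > 0) - 1L)
  }
  if (df == 0L) return(1)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

## backward elimination against one binary target; shared by V- and W-steps
backward_eliminate <- function(data, target, candidates, threshold = 0.1,
                               engine = "lrt", n_perm = 200L) {
  ## constant columns cannot carry information; drop them up front
  const <- candidates[vapply(candidates, function(v)
    length(unique(data[[v]])) < 2L, logical(1))]
  current <- setdiff(candidates, const)
  steps <- list()
  if (length(const)) {
    steps[[length(steps) + 1L]] <- data.frame(
      dropped = const, p_value = NA_real_, reason = "constant column",
      stringsAsFactors = FALSE)
  }
  while (length(current) > 0L) {
    p <- vapply(current, function(v)
      ci_test(data, target, v, setdiff(current, v), engine, n_perm),
      numeric(1))
    worst <- max(p)
    if (worst <= threshold) break
    ## ties: largest p, then lexicographic name
    cand <- sort(current[p == worst])[1L]
    steps[[length(steps) + 1L]] <- data.frame(
      dropped = cand, p_value = worst, reason = "conditionally independent",
      stringsAsFactors = FALSE)
    current <- setdiff(current, cand)
  }
  list(selected = sort(current),
       steps = do.call(rbind, c(steps, list(make.row.names = FALSE))))
}

#' Select the outcome-predictive minimal covariate set V
#'
#' Backward elimination over the candidate pool: at each step, the covariate
#' whose conditional-independence test with the outcome given the remaining
#' covariates has the largest p-value above the threshold is dropped; the
#' procedure stops when every remaining covariate tests dependent. The
#' result V satisfies (empirically) that the outcome is conditionally
#' independent of the discarded covariates given V.
#'
#' @param data data.frame of candidate covariates.
#' @param y 0/1 outcome vector.
#' @param candidates column names forming the pool C.
#' @param threshold elimination threshold on the p-value (default 0.10).
#' @param engine,n_perm passed to [ci_test()].
#' @return list with `V` (selected names) and `steps` (elimination log).
#' @export
select_outcome_set <- function(data, y, candidates = names(data),
                               threshold = 0.1, engine = "lrt",
                               n_perm = 200L) {
  stopifnot(length(candidates) >= 1L)
  r <- backward_eliminate(data, y, candidates, threshold, engine, n_perm)
  list(V = r$selected, steps = r$steps)
}

#' Select the exposure-linked minimal subset W of V
#'
#' Same backward-elimination contract as [select_outcome_set()], but testing
#' conditional independence with the binary exposure, restricted to V. The
#' returned W (a subset of V by construction) is the adjustment set used for
#' targeted estimation.
#'
#' @param data data.frame of covariates.
#' @param g 0/1 exposure vector.
#' @param V covariate names from [select_outcome_set()].
#' @param threshold,engine,n_perm as in [select_outcome_set()].
#' @return list with `W` (selected names) and `steps`.
#' @export
select_exposure_set <- function(data, g, V, threshold = 0.1, engine = "lrt",
                                n_perm = 200L) {
  if (length(V) == 0L) return(list(W = character(), steps = NULL))
  r <- backward_eliminate(data, g, V, threshold, engine, n_perm)
  list(W = r$selected, steps = r$steps)
}

#' Minimal confounder set for one gene: the nested V/W reduction
#'
#' Runs the outcome-side reduction to V over the full covariate pool, then
#' the exposure-side reduction of V to W. W is the adjustment set passed to
#' targeted estimation; V is reported for diagnostics.
#'
#' @param data data.frame of covariates (other candidate genes' exposure
#'   indicators plus clinical covariates).
#' @param y 0/1 outcome vector.
#' @param g 0/1 exposure vector for the gene under study.
#' @param candidates covariate pool; must not contain the gene itself.
#' @param threshold,engine,n_perm as in [ci_test()].
#' @return list of class `"confounder_sets"`: `V`, `W`, `steps_V`,
#'   `steps_W`.
#' @export
select_confounders <- function(data, y, g, candidates = names(data),
                               threshold = 0.1, engine = "lrt",
                               n_perm = 200L) {
  v <- select_outcome_set(data, y, candidates, threshold, engine, n_perm)
  w <- select_exposure_set(data, g, v$V, threshold, engine, n_perm)
  structure(list(V = v$V, W = w$W, steps_V = v$steps, steps_W = w$steps),
            class = "confounder_sets")
}
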