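#' Marginal odds ratio from two counterfactual risks
#'
#' `MOR = [EY1 * (1 - EY0)] / [(1 - EY1) * EY0]`, the odds ratio formed from
#' the two marginal counterfactual outcome probabilities.
#'
#' @param ey1,ey0 counterfactual risks, strictly inside (0, 1).
#' @return positive real.
#' @examples
#' marginal_odds_ratio(0.5, 0.25)  # 3
#' @export
marginal_odds_ratio <- function(ey1, ey0) {
  stopifnot(is.numeric(ey1), is.numeric(ey0))
  if (any(ey1 <= 0 | ey1 >= 1) || any(ey0 <= 0 | ey0 >= 1)) {
    stop("counterfactual risks must lie strictly inside (0, 1)")
  }
  (ey1 * (1 - ey0)) / ((1 - ey1) * ey0)
}

#' Targeted maximum likelihood estimation of AE, IE and MOR
#'
#' Two-stage plug-in estimator of the effect of a binary exposure G on a
#' binary outcome Y adjusting for covariates W. Initial estimates of the
#' outcome regression `Q(G, W) = E[Y | G, W]` and the propensity score
#' `g(W) = P(G = 1 | W)` come from [superlearner_fit()] (or may be supplied
#' directly). The propensity is truncated to `g_bounds`. A logistic
#' fluctuation with the two clever covariates `H1 = G / g(W)` and
#' `H0 = -(1 - G) / (1 - g(W))` and offset `logit(Q)` updates the outcome
#' regression until the empirical mean of the efficient influence curve is
#' solved (iterated to below `score_tol`). The targeted regression Q* then
#' yields
#' `EY1 = mean(Q*(1, W))`, `EY0 = mean(Q*(0, W))`, the average effect
#' `AE = EY1 - EY0`, individual effects `IE_i = Q*(1, W_i) - Q*(0, W_i)`,
#' and the marginal odds ratio via [marginal_odds_ratio()]. Standard errors
#' come from the efficient influence curve; the MOR interval uses the delta
#' method on the log scale.
#'
#' @param y 0/1 outcome vector.
#' @param g_exposure 0/1 exposure vector.
#' @param w data.frame of adjustment covariates, or NULL/zero-column for an
#'   unadjusted fit.
#' @param q_learners,g_learners Super Learner libraries for the outcome and
#'   propensity models.
#' @param v_folds cross-validation folds for the Super Learners.
#' @param g_bounds truncation interval for the estimated propensity
#'   (default `c(0.025, 0.975)`).
#' @param q_init optional matrix/data.frame with columns `Q0`, `Q1` of
#'   initial outcome predictions, bypassing the Super Learner.
#' @param g_init optional vector of initial propensity predictions.
#' @param seed optional integer seed (drives fold assignment and stochastic
#'   learners).
#' @param sl_control hyperparameter overrides, see [sl_control()].
#' @param max_fluct_iter maximum fluctuation iterations (default 10).
#' @param score_tol tolerance on the mean efficient influence curve
#'   (default 1e-11).
#' @param positivity_warn_frac warn when truncation alters more than this
#'   fraction of propensity values (default 0.1).
#' @return object of class `"tmle_fit"`: `AE`, `se_AE`, `ci_AE`, `p_AE`,
#'   `MOR`, `ci_MOR`, `p_MOR`, `EY1`, `EY0`, `IE`, `eic_mean`, `epsilon`,
#'   `iterations`, `g_hat`, `g_truncated_frac`, `sl_q`, `sl_g`.
#' @export
tmle_estimate <- function(y, g_exposure, w = NULL,
                          q_learners = c("glm", "glm_interaction", "glmnet",
                                         "xgboost", "random_forest"),
                          g_learners = q_learners,
                          v_folds = 10L,
                          g_bounds = c(0.025, 0.975),
                          q_init = NULL, g_init = NULL,
                          seed = NULL, sl_control = list(),
                          max_fluct_iter = 10L,
                          score_tol = 1e-11,
                          positivity_warn_frac = 0.1) {
  stopifnot(all(y %in% 0:1), all(g_exposure %in% 0:1),
            length(y) == length(g_exposure),
            length(g_bounds) == 2L, g_bounds[1] > 0, g_bounds[2] < 1,
            g_bounds[1] < g_bounds[2])
  n <- length(y)
  if (all(g_exposure == 1L) || all(g_exposure == 0L)) {
    stop("all samples in one exposure arm: effects are not identifiable ",
         "(positivity violation)")
  }
  if (is.null(w) || NCOL(w) == 0L) {
    w <- data.frame(row.names = seq_len(n))
  }
  w <- as.data.frame(w)
  stopifnot(nrow(w) == n)
  no_cov <- ncol(w) == 0L

  sl_q <- NULL; sl_g <- NULL
  ## --- initial outcome regression -----------------------------------------
  if (!is.null(q_init)) {
    q_init <- as.matrix(q_init)
    stopifnot(ncol(q_init) == 2L, nrow(q_init) == n)
    q0 <- clip_prob(q_init[, 1]); q1 <- clip_prob(q_init[, 2])
  } else if (no_cov) {
    q0 <- rep(clip_prob(mean(y[g_exposure == 0L])), n)
    q1 <- rep(clip_prob(mean(y[g_exposure == 1L])), n)
  } else {
    xq <- cbind(data.frame(..g = g_exposure), w)
    sl_q <- superlearner_fit(xq, y, q_learners, v_folds,
                             seed = if (is.null(seed)) NULL
                                    else derive_seed(seed, "Q"),
                             control = sl_control)
    q1 <- predict(sl_q, cbind(data.frame(..g = 1L), w))
    q0 <- predict(sl_q, cbind(data.frame(..g = 0L), w))
  }

  ## --- initial propensity -------------------------------------------------
  if (!is.null(g_init)) {
    stopifnot(length(g_init) == n)
    g_raw <- g_init
  } else if (no_cov) {
    g_raw <- rep(mean(g_exposure), n)
  } else {
    sl_g <- superlearner_fit(w, g_exposure, g_learners, v_folds,
                             seed = if (is.null(seed)) NULL
                                    else derive_seed(seed, "g"),
                             control = sl_control)
    g_raw <- predict(sl_g, w)
  }
  g_hat <- pmin(pmax(g_raw, g_bounds[1]), g_bounds[2])
  trunc_frac <- mean(g_raw != g_hat)
  if (trunc_frac > positivity_warn_frac) {
    warning(sprintf(paste0("possible positivity violation: %.1f%% of ",
                           "propensity values truncated to [%g, %g]"),
                    100 * trunc_frac, g_bounds[1], g_bounds[2]))
  }

  ## --- logistic fluctuation along the clever covariates -------------------
  h1 <- g_exposure / g_hat
  h0 <- -(1 - g_exposure) / (1 - g_hat)
  eps_total <- c(h0 = 0, h1 = 0)
  iter <- 0L
  repeat {
    q_obs <- ifelse(g_exposure == 1L, q1, q0)
    score <- c(mean(h0 * (y - q_obs)), mean(h1 * (y - q_obs)))
    if (max(abs(score)) < score_tol || iter >= max_fluct_iter) break
    iter <- iter + 1L
    off <- logit(clip_prob(q_obs))
    suppressWarnings(
      fl <- stats::glm(y ~ 0 + h0 + h1 + offset(off),
                       family = stats::binomial(),
                       control = stats::glm.control(epsilon = 1e-14,
                                                    maxit = 100)))
    eps <- stats::coef(fl)
    eps[is.na(eps)] <- 0
    eps_total <- eps_total + eps
    ## update both counterfactual predictions along the submodel
    q1 <- clip_prob(expit(logit(clip_prob(q1)) + eps[["h1"]] / g_hat))
    q0 <- clip_prob(expit(logit(clip_prob(q0)) - eps[["h0"]] / (1 - g_hat)))
  }

  ## --- plug-in estimates and influence-curve inference --------------------
  ey1 <- mean(q1); ey0 <- mean(q0)
  ie <- q1 - q0
  ae <- ey1 - ey0
  q_obs <- ifelse(g_exposure == 1L, q1, q0)
  h_a <- h1 + h0                       # G/g - (1-G)/(1-g)
  d_ae <- h_a * (y - q_obs) + ie - ae
  se_ae <- stats::sd(d_ae) / sqrt(n)
  z_ae <- ae / se_ae
  p_ae <- 2 * stats::pnorm(-abs(z_ae))

  ## components for EY1 and EY0 separately, for the log-MOR delta method
  d1 <- h1 * (y - q_obs) + q1 - ey1
  d0 <- -h0 * (y - q_obs) + q0 - ey0
  mor <- marginal_odds_ratio(ey1, ey0)
  d_logmor <- d1 / (ey1 * (1 - ey1)) - d0 / (ey0 * (1 - ey0))
  se_logmor <- stats::sd(d_logmor) / sqrt(n)
  z_mor <- log(mor) / se_logmor
  p_mor <- 2 * stats::pnorm(-abs(z_mor))

  structure(list(
    AE = ae, se_AE = se_ae,
    ci_AE = ae + c(-1.96, 1.96) * se_ae,
    p_AE = p_ae,
    MOR = mor,
    ci_MOR = exp(log(mor) + c(-1.96, 1.96) * se_logmor),
    p_MOR = p_mor,
    se_log_MOR = se_logmor,
    EY1 = ey1, EY0 = ey0, IE = ie,
    eic_mean = mean(d_ae),
    epsilon = eps_total, iterations = iter,
    g_hat = g_hat, g_truncated_frac = trunc_frac,
    n = n, sl_q = sl_q, sl_g = sl_g), class = "tmle_fit")
}

#' @export
print.tmle_fit <- function(x, ...) {
  cat(sprintf("Targeted maximum likelihood fit (n = %d)\n", x$n))
  cat(sprintf("  AE  = %.4f  (95%% CI %.4f, %.4f)  p = %.4g\n",
              x$AE, x$ci_AE[1], x$ci_AE[2], x$p_AE))
  cat(sprintf("  MOR = %.4f  (95%% CI %.4f, %.4f)  p = %.4g\n",
              x$MOR, x$ci_MOR[1], x$ci_MOR[2], x$p_MOR))
  cat(sprintf("  EY1 = %.4f  EY0 = %.4f  fluctuation iterations = %d\n",
              x$EY1, x$EY0, x$iterations))
  invisible(x)
}

#' Targeted estimation for a batch of candidate genes
#'
#' One TMLE fit per candidate gene, with the gene's median-dichotomized
#' expression as exposure and its selected confounder set as adjustment
#' covariates. Per-gene seeds are derived from the global seed and the gene
#' id, so results are invariant to the order of the candidate list. A
#' failure in one gene is recorded and never aborts the batch.
#'
#' @param candidate_genes character vector of gene ids.
#' @param exposures samples x genes matrix of 0/1 dichotomized expression
#'   (e.g. from [screen_candidates()]).
#' @param covariate_data data.frame of all potential adjustment columns,
#'   rows aligned with `exposures`.
#' @param y 0/1 outcome vector aligned with rows.
#' @param confounder_sets named list (per gene) of `"confounder_sets"`
#'   objects or character vectors naming that gene's adjustment set W.
#' @param seed global integer seed.
#' @param ... further arguments to [tmle_estimate()].
#' @return list with `table` (data.frame: gene, MOR, ci, p_MOR, AE, ci,
#'   p_AE, n_confounders, error) and `fits` (named list of `tmle_fit`
#'   objects).
#' @export
run_per_gene <- function(candidate_genes, exposures, covariate_data, y,
                         confounder_sets, seed = 1L, ...) {
  tab <- list(); fits <- list()
  for (gene in candidate_genes) {
    wset <- confounder_sets[[gene]]
    if (inherits(wset, "confounder_sets")) wset <- wset$W
    wset <- intersect(wset %||% character(), names(covariate_data))
    fit <- tryCatch(
      tmle_estimate(y, exposures[, gene],
                    covariate_data[, wset, drop = FALSE],
                    seed = derive_seed(seed, gene), ...),
      error = function(e) e)
    if (inherits(fit, "error")) {
      tab[[gene]] <- data.frame(gene = gene, MOR = NA_real_,
                                MOR_ci_low = NA_real_, MOR_ci_high = NA_real_,
                                p_MOR = NA_real_, AE = NA_real_,
                                AE_ci_low = NA_real_, AE_ci_high = NA_real_,
                                p_AE = NA_real_,
                                n_confounders = length(wset),
                                error = conditionMessage(fit),
                                stringsAsFactors = FALSE)
    } else {
      fits[[gene]] <- fit
      tab[[gene]] <- data.frame(gene = gene, MOR = fit$MOR,
                                MOR_ci_low = fit$ci_MOR[1],
                                MOR_ci_high = fit$ci_MOR[2],
                                p_MOR = fit$p_MOR, AE = fit$AE,
                                AE_ci_low = fit$ci_AE[1],
                                AE_ci_high = fit$ci_AE[2],
                                p_AE = fit$p_AE,
                                n_confounders = length(wset),
                                error = NA_character_,
                                stringsAsFactors = FALSE)
    }
  }
  table <- if (length(tab)) do.call(rbind, c(tab, list(make.row.names = FALSE)))
  else data.frame(gene = character(), MOR = numeric(),
                  MOR_ci_low = numeric(), MOR_ci_high = numeric(),
                  p_MOR = numeric(), AE = numeric(), AE_ci_low = numeric(),
                  AE_ci_high = numeric(), p_AE = numeric(),
                  n_confounders = integer(), error = character(),
                  stringsAsFactors = FALSE)
  list(table = table, fits = fits)
}
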