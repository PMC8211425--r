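#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' generator emulates the statistical structure the pipeline assumes in real
#' bulk tumor RNA-seq cohorts: negative-binomial read counts with latent
#' immune/stromal signature structure, clinical confounders acting on both a
#' binary exposure (high expression of a designated gene) and a binary
#' mortality outcome, and an outcome drawn from a known logistic structural
#' model so that the true counterfactual effects are computable.
#'
#' Default cohort conditions mirror a TCGA ovarian serous cancer style
#' cohort: 285 analyzable samples with ~40% 3-year mortality, a binary
#' advanced-disease confounder and a continuous (standardized age)
#' confounder that each raise both the probability of high expression and
#' the probability of death, and a protective structural gene effect of
#' -0.7 on the mortality logit (a marginal risk difference near -0.15 at the
#' baseline risk).
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes.
#' @param n_signature_genes genes per signature (immune and stromal each).
#' @param nb_dispersion negative-binomial dispersion alpha, with
#'   `Var = mu + alpha * mu^2`.
#' @param base_mean_log_range range of per-gene log2 mean expression, drawn
#'   uniformly.
#' @param signature_fold_change multiplicative elevation of signature-gene
#'   means in samples whose latent immune (resp. stromal) state is high.
#' @param latent_correlation probability that a sample's latent stromal
#'   state copies its immune state (0 = independent states; immune and
#'   stromal infiltration co-vary in real tumors, which is what makes
#'   direction-concordant shared DEGs non-empty).
#' @param confounders list of confounder specifications; each element is a
#'   list with fields `name`, `dist` (`"binary"` or `"normal"`), distribution
#'   parameters (`p` for binary; `mean`, `sd` for normal), `coef_exposure`
#'   and `coef_outcome` (logit-scale coefficients).
#' @param gene_effect_logit structural effect of the exposure (high
#'   expression of the causal gene) on the mortality logit.
#' @param outcome_intercept,exposure_intercept logit-scale intercepts.
#' @param causal_gene id of the designated exposure gene (default
#'   `"gene_0001"`, kept out of both signatures unless
#'   `causal_in_signatures`).
#' @param causal_fold_change fold elevation of the causal gene's mean when
#'   the structural exposure is 1 (makes median-dichotomized expression a
#'   near-faithful readout of the structural exposure).
#' @param latent_exposure_coef logit-scale coefficient of each latent TME
#'   state on the exposure. The latent states have no outcome path, so they
#'   are instruments rather than confounders and the analytic truth is
#'   unaffected; a positive value ties high expression of the causal gene to
#'   immune/stromal infiltration, which is what lets the gene surface as a
#'   score-group DEG in the full pipeline.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a validated list of class `"sim_config"`.
#' @export
simulation_config <- function(n_samples = 285L,
                              n_genes = 2000L,
                              n_signature_genes = 50L,
                              nb_dispersion = 0.2,
                              base_mean_log_range = c(3, 9),
                              signature_fold_change = 4,
                              latent_correlation = 0,
                              confounders = default_confounders(),
                              gene_effect_logit = -0.7,
                              outcome_intercept = stats::qlogis(0.4),
                              exposure_intercept = 0,
                              causal_gene = "gene_0001",
                              causal_fold_change = 6,
                              latent_exposure_coef = 0,
                              seed = 1L) {
  stopifnot(n_samples >= 1, n_genes >= 1,
            n_signature_genes >= 0,
            2 * n_signature_genes <= n_genes,
            nb_dispersion > 0,
            length(base_mean_log_range) == 2L,
            base_mean_log_range[1] <= base_mean_log_range[2],
            signature_fold_change > 0, causal_fold_change > 0,
            latent_correlation >= 0, latent_correlation <= 1)
  if (n_samples <= 0 || n_genes <= 0) stop("non-positive cohort dimensions")
  for (cf in confounders) {
    stopifnot(is.list(cf), !is.null(cf$name), !is.null(cf$dist),
              cf$dist %in% c("binary", "normal"),
              is.numeric(cf$coef_exposure), is.numeric(cf$coef_outcome))
  }
  cfg <- list(n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              n_signature_genes = as.integer(n_signature_genes),
              nb_dispersion = nb_dispersion,
              base_mean_log_range = base_mean_log_range,
              signature_fold_change = signature_fold_change,
              latent_correlation = latent_correlation,
              confounders = confounders,
              gene_effect_logit = gene_effect_logit,
              outcome_intercept = outcome_intercept,
              exposure_intercept = exposure_intercept,
              causal_gene = causal_gene,
              causal_fold_change = causal_fold_change,
              latent_exposure_coef = latent_exposure_coef,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Default confounder specification: one binary, one continuous
#'
#' A binary advanced-disease indicator (prevalence 0.5) and a standardized
#' continuous age variable, each shifting both the exposure and the outcome
#' logit upward — the classic positive-confounding pattern that biases a
#' crude comparison toward the null for a protective exposure.
#'
#' @return list of confounder specifications for [simulation_config()].
#' @export
default_confounders <- function() {
  list(
    list(name = "advanced_disease", dist = "binary", p = 0.5,
         coef_exposure = 0.8, coef_outcome = 0.8),
    list(name = "age_std", dist = "normal", mean = 0, sd = 1,
         coef_exposure = 0.5, coef_outcome = 0.5)
  )
}

## draw the confounder columns as a data.frame
draw_confounders <- function(confounders, n) {
  if (length(confounders) == 0L) {
    return(as.data.frame(matrix(nrow = n, ncol = 0)))
  }
  cols <- lapply(confounders, function(cf) {
    switch(cf$dist,
           binary = stats::rbinom(n, 1L, cf$p %||% 0.5),
           normal = stats::rnorm(n, cf$mean %||% 0, cf$sd %||% 1))
  })
  names(cols) <- vapply(confounders, `[[`, "", "name")
  as.data.frame(cols, optional = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## linear predictor contribution of the confounders
confounder_lp <- function(confounders, z, which = c("exposure", "outcome")) {
  which <- match.arg(which)
  field <- if (which == "exposure") "coef_exposure" else "coef_outcome"
  lp <- numeric(nrow(z))
  for (cf in confounders) lp <- lp + cf[[field]] * z[[cf$name]]
  lp
}

#' Simulate a negative-binomial count matrix
#'
#' Low-level count simulator used by [generate_cohort()] and directly useful
#' for differential-expression calibration experiments. Counts for gene g in
#' sample s are NB with mean `mu[g] * fold[g, s]` and dispersion `alpha`
#' (variance `mu + alpha * mu^2`).
#'
#' @param base_means vector of per-gene base means.
#' @param fold_matrix genes x samples matrix of multiplicative mean shifts
#'   (1 = no shift), or `NULL` for none.
#' @param n_samples number of samples (ignored when `fold_matrix` given).
#' @param dispersion NB dispersion alpha > 0.
#' @param gene_ids,sample_ids optional dimnames.
#' @return integer matrix of counts, genes x samples.
#' @export
simulate_count_matrix <- function(base_means, fold_matrix = NULL,
                                  n_samples = NULL, dispersion = 0.2,
                                  gene_ids = NULL, sample_ids = NULL) {
  stopifnot(all(base_means > 0), dispersion > 0)
  G <- length(base_means)
  if (is.null(fold_matrix)) {
    stopifnot(!is.null(n_samples))
    fold_matrix <- matrix(1, G, n_samples)
  }
  stopifnot(nrow(fold_matrix) == G)
  n <- ncol(fold_matrix)
  mu <- base_means * fold_matrix
  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = 1 / dispersion),
                   nrow = G, ncol = n)
  storage.mode(counts) <- "integer"
  rownames(counts) <- gene_ids %||% sprintf("gene_%04d", seq_len(G))
  colnames(counts) <- sample_ids %||% sprintf("sample_%04d", seq_len(n))
  counts
}

#' Generate a synthetic cohort with known counterfactual effects
#'
#' Draws clinical confounders, a structural binary exposure G (high
#' expression of the designated causal gene) from a logistic model on the
#' confounders, a binary mortality outcome Y from a logistic structural
#' model with the configured gene effect, and an NB count matrix whose
#' signature genes track two latent immune/stromal states and whose causal
#' gene is elevated `causal_fold_change`-fold when G = 1. Survival fields
#' (vital status, overall-survival time in years) are generated consistently
#' with Y under a 3-year horizon so the cohort module's outcome definition
#' recovers Y exactly.
#'
#' The returned `truth` holds the per-sample counterfactual risks
#' `p1 = P(Y = 1 | G = 1, Z)` and `p0 = P(Y = 1 | G = 0, Z)` from the
#' structural model, so `true_IE = p1 - p0`, `true_AE = mean(true_IE)`, and
#' `true_MOR` is the marginal odds ratio formed from `mean(p1)` and
#' `mean(p0)` over the simulated covariates.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (integer genes x samples matrix), `clinical`
#'   (data.frame: sample_id, vital_status, os_time, sample_type, confounder
#'   columns), `signatures` (list of immune/stromal gene-id vectors),
#'   `truth` (list: true_AE, true_MOR, true_EY1, true_EY0, true_IE,
#'   true_confounders, signature_membership, exposure, latent_immune,
#'   latent_stromal).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    n <- cfg$n_samples
    G <- cfg$n_genes
    sample_ids <- sprintf("sample_%04d", seq_len(n))
    gene_ids <- sprintf("gene_%04d", seq_len(G))

    ## latent TME states (instruments for the exposure when
    ## latent_exposure_coef != 0; no outcome path)
    lat_imm <- stats::rbinom(n, 1L, 0.5)
    copy <- stats::runif(n) < cfg$latent_correlation
    lat_str <- ifelse(copy, lat_imm, stats::rbinom(n, 1L, 0.5))

    ## clinical confounders and structural exposure/outcome
    z <- draw_confounders(cfg$confounders, n)
    lp_g <- cfg$exposure_intercept +
      confounder_lp(cfg$confounders, z, "exposure") +
      cfg$latent_exposure_coef * (lat_imm + lat_str - 1)
    g_exp <- stats::rbinom(n, 1L, expit(lp_g))
    lp0 <- cfg$outcome_intercept + confounder_lp(cfg$confounders, z, "outcome")
    p1 <- expit(lp0 + cfg$gene_effect_logit)
    p0 <- expit(lp0)
    p_obs <- ifelse(g_exp == 1L, p1, p0)
    y <- stats::rbinom(n, 1L, p_obs)

    ## survival fields consistent with a 3-year horizon
    os_time <- ifelse(y == 1L, stats::runif(n, 0.1, 2.99),
                      stats::runif(n, 3.01, 10))
    dead_late <- y == 0L & stats::runif(n) < 0.2  # deaths after the horizon
    vital <- ifelse(y == 1L | dead_late, "dead", "alive")

    ## signature structure
    ns <- cfg$n_signature_genes
    membership <- rep("none", G)
    ## causal gene sits outside the signatures unless asked otherwise
    causal_idx <- match(cfg$causal_gene, gene_ids)
    if (is.na(causal_idx)) stop("causal_gene not among generated gene ids")
    pool <- setdiff(seq_len(G), causal_idx)
    imm_idx <- pool[seq_len(ns)]
    str_idx <- pool[ns + seq_len(ns)]
    membership[imm_idx] <- "immune"
    membership[str_idx] <- "stromal"

    base_mu <- 2^stats::runif(G, cfg$base_mean_log_range[1],
                              cfg$base_mean_log_range[2])
    fold <- matrix(1, G, n)
    fc <- cfg$signature_fold_change
    fold[imm_idx, ] <- fold[imm_idx, , drop = FALSE] *
      outer(rep(1, length(imm_idx)), fc^lat_imm)
    fold[str_idx, ] <- fold[str_idx, , drop = FALSE] *
      outer(rep(1, length(str_idx)), fc^lat_str)
    fold[causal_idx, ] <- fold[causal_idx, ] * cfg$causal_fold_change^g_exp

    counts <- simulate_count_matrix(base_mu, fold,
                                    dispersion = cfg$nb_dispersion,
                                    gene_ids = gene_ids,
                                    sample_ids = sample_ids)

    clinical <- data.frame(sample_id = sample_ids,
                           vital_status = vital,
                           os_time = os_time,
                           sample_type = "primary",
                           stringsAsFactors = FALSE)
    clinical <- cbind(clinical, z)

    true_ie <- p1 - p0
    names(true_ie) <- sample_ids
    ey1 <- mean(p1); ey0 <- mean(p0)
    conf_names <- vapply(cfg$confounders, `[[`, "", "name")
    is_conf <- vapply(cfg$confounders, function(cf)
      cf$coef_exposure != 0 && cf$coef_outcome != 0, logical(1))
    truth <- list(
      true_AE = mean(true_ie),
      true_MOR = if (ey1 > 0 && ey1 < 1 && ey0 > 0 && ey0 < 1)
        marginal_odds_ratio(ey1, ey0) else NA_real_,
      true_EY1 = ey1, true_EY0 = ey0,
      true_IE = true_ie,
      p1 = stats::setNames(p1, sample_ids),
      p0 = stats::setNames(p0, sample_ids),
      true_confounders = conf_names[is_conf],
      signature_membership = stats::setNames(membership, gene_ids),
      exposure = stats::setNames(g_exp, sample_ids),
      outcome = stats::setNames(y, sample_ids),
      latent_immune = stats::setNames(lat_imm, sample_ids),
      latent_stromal = stats::setNames(lat_str, sample_ids))

    signatures <- list(immune = gene_ids[imm_idx], stromal = gene_ids[str_idx])
    list(counts = counts, clinical = clinical, signatures = signatures,
         truth = truth)
  })
}

#' Analytic counterfactual truth by enumeration over discrete confounders
#'
#' Computes the population AE, EY1/EY0 and MOR implied by a simulation
#' configuration by enumerating the joint support of its (all-discrete)
#' confounders and averaging the two counterfactual outcome probabilities
#' analytically. The result depends only on the structural parameters, never
#' on the seed.
#'
#' @param config a [simulation_config()] whose confounders are all binary.
#' @return list with `true_AE`, `true_EY1`, `true_EY0`, `true_MOR`.
#' @export
enumerate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfs <- config$confounders
  if (length(cfs) == 0L) {
    p1 <- expit(config$outcome_intercept + config$gene_effect_logit)
    p0 <- expit(config$outcome_intercept)
    return(list(true_AE = p1 - p0, true_EY1 = p1, true_EY0 = p0,
                true_MOR = marginal_odds_ratio(clip_prob(p1), clip_prob(p0))))
  }
  if (!all(vapply(cfs, `[[`, "", "dist") == "binary")) {
    stop("enumeration requires all confounders to be discrete (binary)")
  }
  grid <- expand.grid(rep(list(0:1), length(cfs)))
  names(grid) <- vapply(cfs, `[[`, "", "name")
  pr <- rep(1, nrow(grid))
  for (j in seq_along(cfs)) {
    p <- cfs[[j]]$p %||% 0.5
    pr <- pr * ifelse(grid[[j]] == 1, p, 1 - p)
  }
  lp0 <- config$outcome_intercept + confounder_lp(cfs, grid, "outcome")
  p1 <- expit(lp0 + config$gene_effect_logit)
  p0 <- expit(lp0)
  ey1 <- sum(pr * p1); ey0 <- sum(pr * p0)
  list(true_AE = ey1 - ey0, true_EY1 = ey1, true_EY0 = ey0,
       true_MOR = marginal_odds_ratio(clip_prob(ey1), clip_prob(ey0)))
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes the count matrix as TSV (gene id column + one column per sample),
#' the clinical table as TSV, and the immune/stromal signatures as GMT.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cp <- file.path(dir, "counts.tsv")
  counts_df <- data.frame(gene_id = rownames(cohort$counts),
                          cohort$counts, check.names = FALSE)
  write_tsv(counts_df, cp)
  kp <- file.path(dir, "clinical.tsv")
  write_tsv(cohort$clinical, kp)
  gp <- file.path(dir, "signatures.gmt")
  write_gmt(cohort$signatures, gp)
  invisible(c(counts = cp, clinical = kp, signatures = gp))
}
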