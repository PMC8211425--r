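#' Dichotomize a gene's expression at the cohort median
#'
#' G = 1 (high expression) for samples strictly above the median, otherwise
#' 0 — the same tie rule as [split_by_median()]. The indicator is invariant
#' under strictly monotone transforms of the expression values.
#'
#' @param expr named numeric vector of per-sample expression.
#' @return named integer 0/1 vector.
#' @export
dichotomize_expression <- function(expr) {
  g <- as.integer(split_by_median(expr) == "high")
  names(g) <- names(expr)
  g
}

#' Univariate logistic regression of a binary outcome on one predictor
#'
#' Fits `y ~ x` by maximum likelihood. For binary or continuous predictors a
#' single row is returned; a factor predictor expands into one row per
#' non-reference level (the factor's first level is the reference). Odds
#' ratios are `exp(coef)` with Wald 95% confidence intervals
#' `exp(coef +/- 1.96 * SE)`. Complete or quasi-complete separation is
#' reported through the `separation` flag rather than an error.
#'
#' @param x predictor: numeric vector or factor.
#' @param y 0/1 outcome vector.
#' @param variable name used in the output.
#' @return data.frame: `variable`, `level`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, `separation`.
#' @export
logistic_univariate <- function(x, y, variable = deparse(substitute(x))) {
  stopifnot(length(x) == length(y), all(y %in% 0:1))
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  df <- data.frame(y = y, x = x)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(), data = df))
  sm <- summary(fit)$coefficients
  idx <- setdiff(rownames(sm), "(Intercept)")
  co <- sm[idx, 1]; se <- sm[idx, 2]; p <- sm[idx, 4]
  sep <- abs(co) > 15 | se > 100           # separation heuristic
  lev <- if (is.factor(x)) sub("^x", "", idx) else
    if (all(x %in% 0:1)) "High expression level" else "per unit"
  data.frame(variable = variable,
             level = lev,
             odds_ratio = exp(co),
             ci_low = exp(co - 1.96 * se),
             ci_high = exp(co + 1.96 * se),
             p_value = p,
             separation = sep,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Univariate screening of candidate genes and clinical factors
#'
#' Each differentially expressed gene is median-dichotomized on normalized
#' expression and regressed against the outcome; each clinical covariate is
#' regressed as-is (factors expand to reference-coded levels). A variable is
#' retained when any of its levels has p below `alpha` — so a categorical
#' factor survives as soon as one level is significant.
#'
#' @param deg_genes character vector of candidate gene ids.
#' @param counts genes x samples count matrix over the analysis cohort.
#' @param clinical data.frame of clinical covariates (may be NULL).
#' @param clinical_covariates names of clinical columns to screen.
#' @param y named 0/1 outcome vector aligned with `colnames(counts)`.
#' @param alpha significance threshold (default 0.05).
#' @return list with `results` (all univariate rows), `candidate_genes`
#'   (genes passing), `candidate_clinical` (clinical variables passing) and
#'   `exposures` (matrix of dichotomized expression, samples x genes).
#' @export
screen_candidates <- function(deg_genes, counts, clinical = NULL,
                              clinical_covariates = character(), y,
                              alpha = 0.05) {
  stopifnot(all(names(y) == colnames(counts)))
  expr <- log2_cpm(counts)
  rows <- list()
  exposures <- matrix(NA_integer_, nrow = length(y), ncol = 0,
                      dimnames = list(names(y), NULL))
  for (g in deg_genes) {
    if (!g %in% rownames(expr)) next
    gx <- dichotomize_expression(expr[g, ])
    exposures <- cbind(exposures, gx)
    colnames(exposures)[ncol(exposures)] <- g
    rows[[g]] <- logistic_univariate(gx, y, variable = g)
  }
  for (v in clinical_covariates) {
    xv <- clinical[[v]][match(names(y), clinical$sample_id)]
    if (is.character(xv)) xv <- factor(xv)
    if (is.factor(xv) && nlevels(droplevels(xv)) < 2L) next
    if (is.numeric(xv) && length(unique(xv)) < 2L) next
    rows[[v]] <- logistic_univariate(xv, y, variable = v)
  }
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  sig <- unique(results$variable[results$p_value < alpha & !results$separation])
  list(results = results,
       candidate_genes = intersect(deg_genes, sig),
       candidate_clinical = intersect(clinical_covariates, sig),
       exposures = exposures)
}
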