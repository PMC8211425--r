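#' Sensitivity and specificity of a binary prediction
#'
#' @param pred 0/1 predicted class vector.
#' @param labels 0/1 true class vector (both classes present).
#' @return named vector `c(sensitivity = TP/(TP+FN), specificity =
#'   TN/(TN+FP))`.
#' @export
sensitivity_specificity <- function(pred, labels) {
  stopifnot(all(pred %in% 0:1), all(labels %in% 0:1),
            length(pred) == length(labels))
  if (length(unique(labels)) < 2L) stop("both label classes must be present")
  c(sensitivity = sum(pred == 1 & labels == 1) / sum(labels == 1),
    specificity = sum(pred == 0 & labels == 0) / sum(labels == 0))
}

#' Area under the ROC curve
#'
#' Computed via the rank (Mann-Whitney) formulation, which equals the
#' trapezoidal area under the ROC curve over all thresholds with tied
#' scores contributing 1/2: `AUC = (R1 - n1(n1+1)/2) / (n1 * n0)` where R1
#' is the rank sum of the positive class.
#'
#' @param score numeric risk score (higher = more positive).
#' @param labels 0/1 class vector (both classes present).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(score, labels) {
  stopifnot(is.numeric(score), all(labels %in% 0:1),
            length(score) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both label classes must be present")
  r <- rank(score, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Combine several genes into one discriminatory score
#'
#' Dichotomizes each gene's expression at its median and fits an in-sample
#' logistic regression of the labels on the k indicators; the combined score
#' is the fitted linear predictor. The fusion rule is deliberately simple
#' and swappable — any monotone score can be passed to [roc_auc()] instead.
#'
#' @param expr samples x genes numeric matrix of expression for the k genes.
#' @param labels 0/1 outcome vector.
#' @return list with `score` (linear predictor per sample), `fit` (the glm),
#'   `auc`, and `separation` flag.
#' @export
combine_genes <- function(expr, labels) {
  expr <- as.matrix(expr)
  stopifnot(nrow(expr) == length(labels), ncol(expr) >= 1L)
  gx <- apply(expr, 2, dichotomize_expression)
  d <- data.frame(..y = labels, gx, check.names = TRUE)
  fit <- suppressWarnings(stats::glm(..y ~ ., stats::binomial(), data = d))
  co <- summary(fit)$coefficients
  separation <- any(abs(co[, 1]) > 15) || any(co[, 2] > 100)
  score <- as.numeric(stats::predict(fit, type = "link"))
  list(score = score, fit = fit, auc = roc_auc(score, labels),
       separation = separation)
}

#' Per-gene and combined external validation report
#'
#' For each gene: median-dichotomized expression is used as the predicted
#' class, and sensitivity/specificity against the labels are reported along
#' with the single-gene AUC. The combined row uses [combine_genes()], with
#' the operating point for combined sensitivity/specificity chosen by the
#' Youden index on the combined score.
#'
#' @param expr samples x genes matrix of expression for the validated genes.
#' @param labels 0/1 outcome vector.
#' @param alias_map optional named character vector mapping requested gene
#'   ids to substitute ids present in `colnames(expr)` (e.g. a family-member
#'   probe standing in for an unmeasured gene).
#' @return list with `per_gene` (data.frame: gene, sensitivity, specificity,
#'   auc), `combined` (auc, sensitivity, specificity, threshold) and
#'   `score` (combined score vector).
#' @export
validation_report <- function(expr, labels, alias_map = NULL) {
  expr <- as.matrix(expr)
  if (!is.null(alias_map)) {
    for (want in names(alias_map)) {
      if (!want %in% colnames(expr) && alias_map[[want]] %in% colnames(expr)) {
        colnames(expr)[colnames(expr) == alias_map[[want]]] <- want
      }
    }
  }
  per_gene <- do.call(rbind, lapply(colnames(expr), function(g) {
    gx <- dichotomize_expression(expr[, g])
    ss <- sensitivity_specificity(gx, labels)
    data.frame(gene = g, sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]],
               auc = roc_auc(expr[, g], labels),
               stringsAsFactors = FALSE)
  }))
  comb <- combine_genes(expr, labels)
  ## Youden-optimal operating point on the combined score
  thr <- sort(unique(comb$score))
  youden <- vapply(thr, function(t) {
    ss <- sensitivity_specificity(as.integer(comb$score >= t), labels)
    ss[["sensitivity"]] + ss[["specificity"]] - 1
  }, numeric(1))
  best <- thr[which.max(youden)]
  ss <- sensitivity_specificity(as.integer(comb$score >= best), labels)
  list(per_gene = per_gene,
       combined = list(auc = comb$auc,
                       sensitivity = ss[["sensitivity"]],
                       specificity = ss[["specificity"]],
                       threshold = best,
                       separation = comb$separation),
       score = comb$score)
}
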