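#' Published tumor-residual-disease counts for the TCGA-OV 3-year cohort
#'
#' Dead/alive patient counts by residual-disease category in the published
#' 285-patient TCGA ovarian serous cancer 3-year-mortality cohort, as
#' summarized in its clinicopathologic description. Used to reproduce the
#' reported univariate logistic regression of 3-year mortality on tumor
#' residual disease (reference level "No macroscopic disease").
#'
#' @return integer matrix with rows `dead`/`alive` and one column per
#'   residual-disease category.
#' @export
osc_residual_disease_counts <- function() {
  m <- matrix(c(11L, 27L,
                53L, 85L,
                8L, 12L,
                32L, 25L,
                11L, 21L),
              nrow = 2, dimnames = list(
                c("dead", "alive"),
                c("No macroscopic disease", "1-10 mm", "11-20 mm",
                  ">20 mm", "Unknown")))
  m
}

#' Expand a dead/alive category count table into per-patient data
#'
#' @param counts matrix as returned by [osc_residual_disease_counts()].
#' @return data.frame with `y` (1 = dead) and `x` (factor with the table's
#'   categories, first column as reference level).
#' @export
expand_count_table <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == 2L)
  lev <- colnames(counts)
  y <- integer(); x <- character()
  for (j in seq_len(ncol(counts))) {
    y <- c(y, rep(1L, counts["dead", j]), rep(0L, counts["alive", j]))
    x <- c(x, rep(lev[j], sum(counts[, j])))
  }
  data.frame(y = y, x = factor(x, levels = lev))
}
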